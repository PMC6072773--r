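test_that("the packaged surrogate network validates and contains both mediators", {
  net <- surrogate_network()
  expect_s3_class(net, "network_model")
  expect_true(all(c("PGE2", "wLTB4") %in% net$species$name))
  expect_gte(length(net$feedback), 2)
  expect_identical(net$provenance, "packaged_surrogate")
})

test_that("effective Km follows the additive competitive-inhibition closed forms", {
  r <- mm_reaction("cox", "AA", "PGE2", "COX-2", vmax = 6, km = 50)
  expect_identical(effective_km(r, list(), 0), 50)
  # single inhibitor at I = Ki doubles Km
  s1 <- const_signal(conc = 0.5, ki = 0.5)
  expect_equal(effective_km(r, list(s1), 10), 100)
  # the MM rate at S = Km is then Vmax/3
  S <- 50
  v <- r$vmax * S / (effective_km(r, list(s1), 10) + S)
  expect_equal(v, r$vmax / 3)
  # two inhibitors each at I = Ki triple Km (term-by-term additivity)
  s2 <- const_signal(conc = 2, ki = 2)
  expect_equal(effective_km(r, list(s1, s2), 10), 150)
  both <- effective_km(r, list(s1, s2), 10)
  each <- effective_km(r, list(s1), 10) + effective_km(r, list(s2), 10) -
    r$km
  expect_equal(both, each)
  # signals for other enzymes are ignored
  s3 <- const_signal(conc = 10, enzyme = "5-LOX", ki = 0.1)
  expect_identical(effective_km(r, list(s3), 10), 50)
})

test_that("without inhibitors the pre-equilibrated network stays at steady state", {
  net <- surrogate_network()
  p <- simulate_network(net, list(), span = 360)
  for (sp in c("AA", "PGE2", "LTB4", "wLTB4")) {
    drift <- diff(range(p[[sp]])) / mean(p[[sp]])
    expect_lt(drift, 0.001)
  }
})

test_that("two control runs are bit-identical and Ki -> infinity recovers the control", {
  net <- surrogate_network()
  c1 <- simulate_network(net, list(), span = 360)
  c2 <- simulate_network(net, list(), span = 360)
  expect_identical(c1$PGE2, c2$PGE2)
  expect_identical(c1$wLTB4, c2$wLTB4)
  weak <- inhibitor_signal("x", "COX-2", ki = 1e9,
                           conc = function(t) rep(1, length(t)))
  t1 <- simulate_network(net, list(weak), span = 360)
  expect_equal(t1$PGE2, c1$PGE2, tolerance = 1e-7)
  expect_equal(t1$wLTB4, c1$wLTB4, tolerance = 1e-7)
})

test_that("treated and control trajectories are identical before the 5-min onset", {
  net <- surrogate_network()
  sig <- inhibitor_signal("x", "COX-2", ki = 0.02,
                          conc = function(t) rep(0.5, length(t)),
                          t_dose = 0, onset_delay = 5)
  ctrl <- simulate_network(net, list(), span = 60)
  trt <- simulate_network(net, list(sig), span = 60)
  pre <- trt$time < 5
  expect_equal(trt$PGE2[pre], ctrl$PGE2[pre], tolerance = 1e-12)
  post <- trt$time > 20
  expect_true(all(trt$PGE2[post] < ctrl$PGE2[post]))
})

test_that("a saturating COX-2 inhibitor sends PGE2 into production-free decay", {
  net <- surrogate_network()
  sig <- const_signal(conc = 1e6, ki = 1e-3)   # I/Ki = 1e9
  trt <- simulate_network(net, list(sig), span = 360)
  # PGE2 decays towards zero with its degradation kinetics
  expect_lt(trt$PGE2[nrow(trt)], 0.01 * trt$PGE2[1])
  expect_true(all(diff(trt$PGE2) <= 1e-9))
  # wLTB4 changes only through network coupling (shunt + feedback relief):
  # bounded, modest rise
  rel <- trt$wLTB4 / trt$wLTB4[1]
  expect_true(all(rel >= 1 - 1e-9))
  expect_lt(max(rel), 2)
})

test_that("increasing inhibitor concentration never increases the COX-2 rate", {
  net <- surrogate_network()
  ctrl <- simulate_network(net, list(), span = 60)
  S <- as.list(ctrl[1, -1])
  cox <- which(vapply(net$reactions, function(r) r$enzyme == "COX-2",
                      logical(1)))
  rates <- vapply(c(0, 0.01, 0.1, 1, 10), function(I) {
    sigs <- if (I > 0) list(const_signal(conc = I, ki = 0.02)) else list()
    aaqsp:::network_rates(net, S, 10, sigs)[cox]
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("the adaptive solution matches brute-force fixed-step Euler integration", {
  net <- surrogate_network()
  sig <- const_signal(conc = 0.2, ki = 0.02)
  prof <- simulate_network(net, list(sig), span = 120, dt = 1)
  # independent fixed-step Euler oracle on the same equations
  h <- 0.005
  y <- setNames(net$species$initial, net$species$name)
  free <- net$species$name[!net$species$boundary]
  keep <- matrix(NA_real_, nrow = 121, ncol = length(y),
                 dimnames = list(NULL, names(y)))
  keep[1, ] <- y
  for (i in seq_len(120 / h)) {
    t <- (i - 1) * h
    v <- aaqsp:::network_rates(net, as.list(y), t, list(sig))
    dy <- setNames(numeric(length(y)), names(y))
    for (j in seq_along(net$reactions)) {
      r <- net$reactions[[j]]
      dy[r$substrate] <- dy[r$substrate] - v[j]
      if (!is.null(r$product)) dy[r$product] <- dy[r$product] + v[j]
    }
    dy[net$species$name[net$species$boundary]] <- 0
    y <- y + h * dy
    tt <- i * h
    if (abs(tt - round(tt)) < h / 2 && round(tt) <= 120)
      keep[round(tt) + 1, ] <- y
  }
  for (sp in c("AA", "PGE2", "wLTB4")) {
    rel <- max(abs(prof[[sp]] - keep[, sp]) / max(abs(keep[, sp])))
    expect_lt(rel, 0.005)
  }
})

test_that("network validation rejects dangling references and missing mediators", {
  sp <- data.frame(name = c("A", "PGE2", "wLTB4"), initial = c(1, 1, 1),
                   boundary = FALSE)
  expect_error(network_model(sp, list(
    mm_reaction("r1", "A", "B", "E", 1, 1))), "unknown species")
  sp2 <- data.frame(name = c("A", "PGE2"), initial = c(1, 1),
                    boundary = FALSE)
  expect_error(network_model(sp2, list()), "wLTB4")
  expect_error(network_model(sp, list(
    mm_reaction("r1", "A", "PGE2", "E", 1, 1)),
    feedback = list(list(regulator = "A", target = "nope", sign = 1,
                         strength = 0.1, k_half = 1))), "feedback target")
})
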