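test_that("spectrum simulation is seed-reproducible and decorrelated", {
  db <- fixture_markers()
  a <- simulate_spectrum(db, "Bos sp.", seed = 3)
  b <- simulate_spectrum(db, "Bos sp.", seed = 3)
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
  c <- simulate_spectrum(db, "Bos sp.", seed = 4)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("simulated spectra satisfy the spectrum invariants", {
  db <- fixture_markers()
  for (seed in c(1, 99)) {
    sp <- simulate_spectrum(db, "Rangifer tarandus", seed = seed,
                            deamidation_fraction = 0.3)
    expect_true(all(diff(sp$mz) > 0))
    expect_true(all(sp$intensity >= 0))
  }
  expect_error(simulate_spectrum(db, "Tyrannosaurus rex"), "not in marker")
})

test_that("the simulators do not disturb the caller's random stream", {
  set.seed(123)
  first <- runif(1)
  set.seed(123)
  invisible(simulate_spectrum(fixture_markers(), "Bos sp.", seed = 5,
                              mz_range = c(1000, 1050)))
  expect_identical(runif(1), first)
})

test_that("the high-mass cutoff suppresses heavy markers", {
  db <- fixture_markers()
  sp <- simulate_spectrum(db, "Bos sp.", seed = 6, snr = 15)
  pk <- pick_peaks(sp)
  expect_false(any(pk$mz > 2500))
  full <- simulate_spectrum(db, "Bos sp.", seed = 6, snr = 15,
                            mass_cutoff = Inf)
  expect_true(any(pick_peaks(full)$mz > 2500))
})

test_that("zero-SNR simulation yields no peaks and no identification", {
  db <- fixture_markers()
  sp <- simulate_spectrum(db, "Bos sp.", seed = 2, snr = 0)
  pk <- pick_peaks(sp)
  expect_equal(nrow(pk), 0)
  expect_equal(assign_taxon(pk, db)$status, "unidentifiable")
})

test_that("assemblage simulation is seeded and respects degenerate frequencies", {
  groups <- tibble::tibble(group = c("a", "b", "c"), freq = c(1, 0, 0))
  sim <- simulate_assemblage(groups, n_ribs = 20, n_obs = 5, seed = 1)
  expect_equal(unname(sim$assemblage$ribs), c(20L, 0L, 0L))
  expect_equal(unname(sim$obs), c(5L, 0L, 0L))

  g2 <- tibble::tibble(group = c("m", "lb"), freq = c(0.9, 0.1))
  s1 <- simulate_assemblage(g2, 40, 3, seed = 7)
  s2 <- simulate_assemblage(g2, 40, 3, seed = 7)
  expect_identical(s1$obs, s2$obs)
})

test_that("null-hypothesis draws match the multinomial likelihood", {
  g <- tibble::tibble(group = c("medium", "large bovid"),
                      freq = c(38, 4) / 42)
  hits <- vapply(1:2000, function(s) {
    sim <- simulate_assemblage(g, n_ribs = 42, n_obs = 3,
                               hypothesis = "h0", seed = s)
    unname(sim$obs["large bovid"]) == 3L
  }, logical(1))
  p_hat <- mean(hits)
  prof <- tibble::tibble(group = g$group, p = g$freq)
  p_exact <- multinomial_likelihood(c("large bovid" = 3), prof)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(p_hat - p_exact), 3 * se + 1e-12)
})

test_that("selective-hypothesis draws match the DM likelihood", {
  g <- tibble::tibble(group = c("a", "b"), freq = c(0.5, 0.5))
  alpha <- c(a = 2, b = 3)
  counts <- vapply(1:3000, function(s) {
    sim <- simulate_assemblage(g, 10, 3, hypothesis = "ha", alpha = alpha,
                               seed = s)
    unname(sim$obs["a"])
  }, integer(1))
  model <- selectivity_model(
    tibble::tibble(group = c("a", "b"), mass_kg = exp(c(2, 3))), c = 1
  )
  probs <- vapply(0:3, function(k) {
    dirichlet_multinomial_likelihood(c(a = k, b = 3 - k), model)
  }, numeric(1))
  obs_tab <- tabulate(counts + 1, nbins = 4)
  chi <- suppressWarnings(chisq.test(obs_tab, p = probs))
  expect_gt(chi$p.value, 1e-4)
})

test_that("packaged assemblage fixtures reproduce the printed totals", {
  ap <- read_assemblage(zoomsel_extdata("assemblage_abri_peyrony.tsv"))
  expect_equal(sum(ap$nisp[ap$layer == "L-3A"]), 68)
  expect_equal(sum(ap$nisp[ap$layer == "L-3B"]), 541)
  expect_equal(ap$nisp[ap$layer == "L-3B" & ap$taxon == "Rangifer tarandus"],
               264L)

  pech <- read_assemblage(zoomsel_extdata("assemblage_pech1.tsv"))
  expect_equal(sum(pech$nisp), 642)
  expect_equal(pech$nisp[pech$taxon == "Cervus elaphus"], 327L)
})

test_that("fixture rib tallies reproduce the printed rib percentages", {
  ap <- read_assemblage(zoomsel_extdata("assemblage_abri_peyrony.tsv"))
  l3a <- ap[ap$layer == "L-3A" & ap$ribs > 0, ]
  expect_equal(round(100 * l3a$ribs / sum(l3a$ribs)), c(40, 40, 20))
  l3b <- ap[ap$layer == "L-3B" & ap$ribs > 0, ]
  expect_equal(round(100 * l3b$ribs / sum(l3b$ribs)), c(2, 88, 7, 2))
})

test_that("the marker fixture anchors P1 and the large-bovid A marker", {
  db <- fixture_markers()
  p1 <- db$mz[db$taxon == "Bos sp." & db$marker == "P1"]
  expect_equal(marker_label(p1), 1105L)
  expect_equal(p1, mz_protonated("GVQGPPGPAGPR", 1), tolerance = 5e-4)
  a <- db$mz[db$taxon == "Bos sp." & db$marker == "A"]
  expect_equal(marker_label(a), 1208L)
})
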