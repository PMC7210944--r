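test_that("rib profiles pool categories and normalise", {
  a <- tibble::tibble(
    taxon = c("red deer/reindeer", "Bison/Bos", "large ungulate"),
    nisp = c(22L, 10L, 10L), ribs = c(2L, 2L, 1L),
    group = c("medium ungulate", "large bovid", "large bovid")
  )
  prof <- rib_profile(a)
  expect_equal(prof$p[prof$group == "large bovid"], 0.6)
  expect_equal(sum(prof$p), 1, tolerance = 1e-12)

  single <- tibble::tibble(taxon = "x", nisp = 5L, ribs = 5L, group = "x")
  expect_equal(rib_profile(single)$p, 1)

  ident <- tibble::tibble(taxon = letters[1:3], nisp = c(1L, 1L, 2L),
                          ribs = c(1L, 1L, 2L), group = letters[1:3])
  expect_equal(rib_profile(ident)$p, c(0.25, 0.25, 0.5))

  none <- tibble::tibble(taxon = "x", nisp = 3L, ribs = 0L, group = "x")
  expect_error(rib_profile(none), "no ribs")
})

test_that("multinomial likelihood matches closed form and edge cases", {
  prof <- tibble::tibble(group = c("medium", "large bovid"), p = c(0.4, 0.6))
  expect_equal(multinomial_likelihood(c("large bovid" = 1), prof), 0.6)
  expect_equal(multinomial_likelihood(c("large bovid" = 0), prof), 1)

  prof2 <- tibble::tibble(group = c("a", "b"), p = c(0.25, 0.75))
  expect_equal(multinomial_likelihood(c(a = 1, b = 2), prof2), 0.421875)

  prof0 <- tibble::tibble(group = c("a", "b"), p = c(1, 0))
  expect_equal(multinomial_likelihood(c(b = 1), prof0), 0)
})

test_that("Dirichlet-multinomial likelihood matches hand-derived values", {
  m <- selectivity_model(
    tibble::tibble(group = c("a", "b"), mass_kg = exp(c(2, 3))), c = 1
  )
  expect_equal(m$alpha, c(2, 3), tolerance = 1e-12)
  # (3!/1!2!) * [G(5)/G(8)] * [G(3)/G(2)] * [G(5)/G(3)] = 12/35
  expect_equal(dirichlet_multinomial_likelihood(c(a = 1, b = 2), m), 12 / 35,
               tolerance = 1e-12)

  # symmetric concentrations, single draw: 1/K
  for (k in 2:4) {
    ms <- selectivity_model(
      tibble::tibble(group = letters[1:k], mass_kg = rep(exp(2), k)), c = 1
    )
    obs <- setNames(c(1, rep(0, k - 1)), letters[1:k])
    expect_equal(dirichlet_multinomial_likelihood(obs, ms), 1 / k,
                 tolerance = 1e-12)
  }
})

test_that("both likelihoods normalise over all outcomes of fixed n", {
  for (k in 2:4) {
    masses <- tibble::tibble(group = letters[1:k],
                             mass_kg = c(30, 120, 600, 700)[1:k])
    model <- selectivity_model(masses, c = 0.7)
    prof <- tibble::tibble(group = letters[1:k],
                           p = (1:k) / sum(1:k))
    for (n in c(1, 3, 5)) {
      counts <- compositions_of(n, k)
      tot_m <- sum(apply(counts, 1, function(cc) {
        multinomial_likelihood(setNames(cc, letters[1:k]), prof)
      }))
      tot_dm <- sum(apply(counts, 1, function(cc) {
        dirichlet_multinomial_likelihood(setNames(cc, letters[1:k]), model)
      }))
      expect_equal(tot_m, 1, tolerance = 1e-10)
      expect_equal(tot_dm, 1, tolerance = 1e-10)
    }
  }
})

test_that("a single observation is invariant to concentration rescaling", {
  masses <- tibble::tibble(group = c("m", "lb"), mass_kg = c(120, 700))
  obs <- c(lb = 1)
  base <- dirichlet_multinomial_likelihood(obs, selectivity_model(masses, 1))
  for (c_scale in c(0.01, 0.5, 3, 250)) {
    expect_equal(
      dirichlet_multinomial_likelihood(obs, selectivity_model(masses, c_scale)),
      base, tolerance = 1e-8
    )
  }
})

test_that("the DM model converges to the multinomial as c grows", {
  masses <- tibble::tibble(group = letters[1:3], mass_kg = c(30, 120, 700))
  model <- selectivity_model(masses, c = 1e6)
  prof <- tibble::tibble(group = letters[1:3],
                         p = log(masses$mass_kg) / sum(log(masses$mass_kg)))
  counts <- compositions_of(4, 3)
  for (r in seq_len(nrow(counts))) {
    obs <- setNames(counts[r, ], letters[1:3])
    dm <- dirichlet_multinomial_likelihood(obs, model)
    mn <- multinomial_likelihood(obs, prof)
    expect_lt(abs(dm - mn) / mn, 1e-3)
  }
})

test_that("posterior odds reproduce the reported layer L-3A value and invert", {
  odds <- posterior_odds(0.6, 0.125, prior_odds = 1)
  expect_equal(odds, 0.125 / 0.6, tolerance = 1e-12)
  expect_equal(round(odds, 1), 0.2)
  expect_equal(posterior_odds(0.3, 0.3), 1)
  expect_equal(posterior_odds(0.2, 0.5) * posterior_odds(0.5, 0.2), 1,
               tolerance = 1e-12)
  expect_warning(expect_equal(posterior_odds(0, 0.5), Inf), "infinite")
  # rounded published likelihoods give 4.11, not the full-precision 4.2
  expect_equal(posterior_odds(0.0009, 0.0037), 4.11, tolerance = 0.01)
})

test_that("the full selection test favours H0 at L-3A and HA at L-3B", {
  masses <- readr::read_tsv(zoomsel_extdata("body_masses_synthetic.tsv"),
                            show_col_types = FALSE)
  resA <- run_selection_test(fixture_assemblage("L-3A"),
                             c("large bovid" = 1), masses)
  expect_equal(resA$lik_h0, 0.6)
  expect_true(all(tidy(resA)$posterior_odds < 1))
  # one observation: both variants give the same HA likelihood
  expect_equal(tidy(resA)$lik_ha[1], tidy(resA)$lik_ha[2], tolerance = 1e-12)

  resB <- run_selection_test(fixture_assemblage("L-3B"),
                             c("large bovid" = 3), masses)
  expect_equal(resB$lik_h0, 0.0009, tolerance = 0.05)
  expect_true(all(tidy(resB)$posterior_odds > 1))
  expect_equal(glance(resB)$favours, "selective")

  # no observations: likelihoods 1, odds equal the prior odds
  res0 <- run_selection_test(fixture_assemblage("L-3A"),
                             c("large bovid" = 0), masses, prior_odds = 0.5)
  expect_equal(res0$lik_h0, 1)
  expect_equal(tidy(res0)$posterior_odds, c(0.5, 0.5))
})

test_that("selection test accessors and report serialisation work", {
  masses <- readr::read_tsv(zoomsel_extdata("body_masses_synthetic.tsv"),
                            show_col_types = FALSE)
  res <- run_selection_test(fixture_assemblage("L-3B"),
                            c("large bovid" = 3), masses)
  td <- tidy(res)
  expect_equal(td$variant, c("strong", "weak"))
  expect_equal(td$posterior_odds, (td$lik_ha / td$lik_h0) * td$prior_odds)
  expect_s3_class(autoplot(res), "ggplot")
  expect_output(print(res), "better supported")

  path <- withr::local_tempfile(fileext = ".json")
  write_selection_report(res, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$lik_h0, res$lik_h0, tolerance = 1e-12)
  expect_equal(length(rep$variants), 2)
})

test_that("masses and observations are validated", {
  masses <- tibble::tibble(group = "medium ungulate", mass_kg = 120)
  expect_error(
    run_selection_test(fixture_assemblage("L-3A"), c("large bovid" = 1), masses),
    "No body mass"
  )
  expect_error(
    selectivity_model(tibble::tibble(group = "x", mass_kg = 0.5)),
    "exceed 1 kg"
  )
  prof <- tibble::tibble(group = "a", p = 1)
  expect_error(multinomial_likelihood(c(zzz = 1), prof), "zzz")
})

test_that("maximum likelihood over c recovers the generating concentration", {
  masses <- tibble::tibble(group = c("medium", "large bovid"),
                           mass_kg = c(120, 700))
  c_true <- 1
  alpha <- c_true * log(masses$mass_kg)
  names(alpha) <- masses$group
  g <- tibble::tibble(group = masses$group, freq = c(0.9, 0.1))
  draws <- purrr::map(1:500, function(s) {
    simulate_assemblage(g, 40, 5, hypothesis = "ha", alpha = alpha,
                        seed = s)$obs
  })
  nll <- function(cc) {
    model <- selectivity_model(masses, c = cc)
    -sum(vapply(draws, function(obs) {
      log(dirichlet_multinomial_likelihood(obs, model))
    }, numeric(1)))
  }
  c_hat <- optimize(nll, c(0.05, 20))$minimum
  expect_gt(c_hat, c_true / 2)
  expect_lt(c_hat, c_true * 2)
})
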