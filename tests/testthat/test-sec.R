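test_that("a single noise-free monomer peak quantifies to fraction 1", {
  tr <- simulate_chromatogram(c(monomer = 50), c(monomer = 8.6))
  tab <- quantify_species(tr, sec_default_windows()["monomer"])
  expect_equal(tab$fraction, 1)
  tab4 <- quantify_species(tr, sec_default_windows())
  expect_equal(tab4$fraction[tab4$species == "monomer"], 1, tolerance = 1e-4)
})

test_that("planted 97/3 monomer-dimer areas are recovered exactly without noise", {
  tr <- simulate_chromatogram(c(dimer = 3, monomer = 97),
                              c(dimer = 7.2, monomer = 8.6))
  tab <- quantify_species(tr, sec_default_windows())
  expect_equal(tab$fraction[tab$species == "monomer"], 0.97, tolerance = 1e-3)
  expect_equal(tab$fraction[tab$species == "dimer"], 0.03, tolerance = 1e-3)
  expect_error(simulate_chromatogram(c(dimer = 3, monomer = 97),
                                     c(dimer = 9, monomer = 8.6)),
               "retention order")
})

test_that("overlapping peaks at 2-sigma separation integrate within 1% of truth", {
  w <- 0.12
  rts <- c(dimer = 8.6 - 2 * w, monomer = 8.6)
  tr <- simulate_chromatogram(c(dimer = 50, monomer = 50), rts, widths = w)
  mid <- mean(rts)
  windows <- list(dimer = c(rts[["dimer"]] - 0.5, mid),
                  monomer = c(mid, rts[["monomer"]] + 0.5))
  tab <- quantify_species(tr, windows)
  # analytic overlap oracle: expected area in each window from Gaussian tails
  expected <- vapply(windows, function(b) {
    sum(50 * (pnorm((b[2] - rts) / w) - pnorm((b[1] - rts) / w)))
  }, numeric(1))
  expect_equal(tab$area, unname(expected), tolerance = 2e-3)
  # equal-area spillover cancels: fractions within 1% of the planted truth
  expect_equal(tab$fraction, c(0.5, 0.5), tolerance = 0.01)
})

test_that("an all-zero trace is rejected", {
  tr <- data.frame(time_min = seq(4, 14, 0.01), mAU = 0)
  expect_error(quantify_species(tr, sec_default_windows()), "not positive")
})

test_that("a four-species composition is recovered within half a point at 0.5% noise", {
  fr <- c(aggregate = 0.02, dimer = 0.05, monomer = 0.88, fragment = 0.05)
  peak_max <- 0.88 * 100 / (0.12 * sqrt(2 * pi))
  tr <- simulate_chromatogram(fr * 100,
                              c(aggregate = 6.0, dimer = 7.2, monomer = 8.6,
                                fragment = 11.0),
                              noise_sd = 0.005 * peak_max, seed = 21)
  tab <- quantify_species(tr, sec_default_windows())
  expect_true(all(abs(tab$fraction - fr[tab$species]) < 0.005))
})

test_that("fractions always sum to one and monomer recovery is monotone", {
  set.seed(12)
  last <- -Inf
  for (m in c(60, 70, 80, 90)) {
    tr <- simulate_chromatogram(c(dimer = 100 - m, monomer = m),
                                c(dimer = 7.2, monomer = 8.6))
    tab <- quantify_species(tr, sec_default_windows())
    expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
    mono <- tab$fraction[tab$species == "monomer"]
    expect_gt(mono, last)
    last <- mono
  }
})

test_that("time-course summaries report the minimum and total monomer change", {
  mk_table <- function(mono) {
    structure(data.frame(
      species = c("aggregate", "dimer", "monomer", "fragment"),
      area = c((1 - mono) / 3, (1 - mono) / 3, mono, (1 - mono) / 3) * 100,
      fraction = c((1 - mono) / 3, (1 - mono) / 3, mono, (1 - mono) / 3)),
      class = c("species_table", "data.frame"))
  }
  const <- list(weeks = c(0, 2, 4), tables = lapply(rep(0.95, 3), mk_table))
  s0 <- summarize_timecourse(const)
  expect_equal(attr(s0, "total_delta_pct"), 0)
  dec <- list(weeks = c(0, 2, 4, 8, 12),
              tables = lapply(c(0.97, 0.965, 0.96, 0.955, 0.95), mk_table))
  s1 <- summarize_timecourse(dec)
  expect_equal(attr(s1, "min_monomer_pct"), 95)
  expect_equal(attr(s1, "total_delta_pct"), -2, tolerance = 1e-9)
  par <- list(weeks = c(0, 2, 4, 8, 12),
              tables = lapply(c(0.89, 0.88, 0.87, 0.86, 0.85), mk_table))
  expect_equal(attr(summarize_timecourse(par), "min_monomer_pct"), 85)
  expect_error(summarize_timecourse(list(weeks = 0, tables = list(mk_table(0.9)))),
               "at least 2")
})
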