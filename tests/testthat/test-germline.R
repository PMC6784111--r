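test_that("percent identity matches direct counts", {
  p <- numbered(parental_vl_seq(), id = "parental")
  expect_equal(percent_identity(p, p, "framework"), 100)
  germs <- load_germline_reference()
  # five planted framework mismatches over the 70 FR1-FR3 positions
  expect_equal(percent_identity(p, germs[["IGKV3-20-like"]], "framework"),
               100 * 65 / 70, tolerance = 1e-9)
  # a single framework mismatch gives 69/70
  one_off <- numbered(mutate_at(canonical_vl(), 10, "G"))
  expect_equal(percent_identity(numbered(canonical_vl()), one_off, "framework"),
               100 * 69 / 70, tolerance = 1e-9)
})

test_that("percent identity is symmetric and X never matches", {
  set.seed(71)
  base <- canonical_vl()
  for (i in 1:5) {
    pos <- sample(setdiff(1:107, 24:34), 6)
    a <- numbered(mutate_at(base, pos[1:3], c("G", "H", "K")))
    b <- numbered(mutate_at(base, pos[4:6], c("W", "Y", "T")))
    expect_equal(percent_identity(a, b, "all"), percent_identity(b, a, "all"))
  }
  with_x <- numbered(mutate_at(base, 15, "X"))
  expect_equal(percent_identity(numbered(base), with_x, "framework"),
               100 * 69 / 70, tolerance = 1e-9)
})

test_that("the closest germline is the planted gene with five framework mismatches", {
  p <- numbered(parental_vl_seq(), id = "parental")
  m <- find_closest_germline(p, load_germline_reference())
  expect_identical(m$germline_id, "IGKV3-20-like")
  expect_equal(m$framework_identity, 100 * 65 / 70, tolerance = 1e-9)
  expect_equal(nrow(m$mismatches), 5)
  expect_identical(m$mismatches$label, c("1", "3", "4", "66", "79"))
  expect_identical(m$mismatches$query, c("D", "Q", "M", "A", "Q"))
  expect_identical(m$mismatches$germline, c("E", "V", "L", "G", "E"))
})

test_that("framework ties break on total V-region identity", {
  q <- numbered(parental_vl_seq(), id = "q")
  # two references with identical frameworks but different CDR agreement
  ref_hi <- numbered(substr(mutate_at(parental_vl_seq(), c(10, 20, 40), c("G", "G", "G")), 1, 95), id = "hi")
  ref_lo <- numbered(substr(mutate_at(mutate_at(parental_vl_seq(), c(10, 20, 40), c("G", "G", "G")), 27, "G"), 1, 95), id = "lo")
  m <- find_closest_germline(q, list(lo = ref_lo, hi = ref_hi))
  expect_equal(percent_identity(q, ref_lo, "framework"),
               percent_identity(q, ref_hi, "framework"))
  expect_identical(m$germline_id, "hi")
})

test_that("positional frequencies reproduce direct counts and normalize", {
  base <- numbered(canonical_vl())
  seqs <- lapply(1:200, function(i) {
    ns <- base
    ns$positions$residue[ns$positions$label == "66"] <-
      if (i <= 122) "G" else if (i <= 172) "A" else "S"
    ns
  })
  prof <- frequency_profile(seqs)
  expect_equal(positional_frequency(prof, "66", "G"), 61)
  expect_equal(positional_frequency(prof, "66", "A"), 25)
  expect_equal(positional_frequency(prof, "66", "W"), 0)
  tot <- sum(vapply(c("G", "A", "S"), function(r) positional_frequency(prof, "66", r), 0))
  expect_equal(tot, 100)
  expect_error(positional_frequency(prof, "999", "G"), "unknown position")
})

test_that("mismatches group into contiguous mutation regions", {
  p <- numbered(parental_vl_seq(), id = "parental")
  m <- find_closest_germline(p, load_germline_reference())
  regions <- group_mismatches(m$mismatches)
  expect_identical(vapply(regions, `[[`, "", "label"), c("1-4", "66", "79"))
  expect_identical(length(group_mismatches(m$mismatches[4, ])), 1L)
  far <- m$mismatches[c(1, 4), ]  # positions 1 and 66
  expect_identical(length(group_mismatches(far)), 2L)
  expect_identical(length(group_mismatches(m$mismatches[0, ])), 0L)
})

test_that("variant enumeration reproduces the published panel naming scheme", {
  cfg <- generator_config(1)
  pan <- generate_variant_panel(cfg)$panel
  expect_equal(nrow(pan), 9)
  expect_identical(pan$name,
                   c("DIQMAQ", "DIQMAQ-K", "EIVLAQ", "DIQMGQ", "DIQMAE",
                     "EIVLGQ", "EIVLAE", "DIQMGE", "EIVLGE"))
  expect_identical(pan$id, 1:9)
  expect_identical(pan$c_terminal_lysine, c(FALSE, TRUE, rep(FALSE, 7)))
  # without the lysine duplicate: the 8 combinations in panel order
  pan8 <- generate_variant_panel(generator_config(1, include_lysine_parental = FALSE))$panel
  expect_identical(pan8$name,
                   c("DIQMAQ", "EIVLAQ", "DIQMGQ", "DIQMAE", "EIVLGQ",
                     "EIVLAE", "DIQMGE", "EIVLGE"))
  # the all-parental entry is the parental sequence unchanged
  expect_identical(pan8$sequence[1], parental_vl_seq())
})

test_that("panel size scales as 2^k and the combinatorial limit holds", {
  p <- numbered(parental_vl_seq(), id = "parental")
  m <- find_closest_germline(p, load_germline_reference())
  regions <- group_mismatches(m$mismatches)
  for (k in 1:3) {
    pan <- enumerate_variants(p, regions[seq_len(k)])
    expect_equal(nrow(pan), 2^k)
    expect_false(anyDuplicated(pan$name) > 0)
  }
  fake <- rep(regions[3], 13)
  expect_error(enumerate_variants(p, fake), "combinatorial limit")
})

test_that("germlining never decreases framework identity to the germline", {
  cfg <- generator_config(1)
  res <- generate_variant_panel(cfg)
  germ <- res$germline_match$germline
  parental_fw <- percent_identity(res$parental, germ, "framework")
  for (i in seq_len(nrow(res$panel))) {
    v <- numbered(res$panel$sequence[i], id = res$panel$name[i])
    expect_gte(percent_identity(v, germ, "framework"), parental_fw)
  }
  # fully germlined variant carries no framework mismatch against the germline
  full <- numbered(res$panel$sequence[9], id = "full")
  m <- find_closest_germline(full, list(`IGKV3-20-like` = germ))
  expect_equal(nrow(m$mismatches), 0)
  expect_equal(m$framework_identity, 100)
})
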