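# shared fixtures, all built in code

canonical_vl <- function() kabat_template("L")
canonical_vh <- function() kabat_template("H")

# canonical kappa VL with one extra CDR-L1 residue (length 12)
vl_with_cdr1_insertion <- function() {
  s <- canonical_vl()
  paste0(substr(s, 1, 28), "S", substr(s, 29, nchar(s)))
}

# replace the residue at a plain Kabat position (string index = position for
# insertion-free sequences)
mutate_at <- function(seq, pos, residue) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- residue
  paste(ch, collapse = "")
}

# parental-style VL: consensus framework carrying the five planted framework
# deviations from the bundled IGKV3-20-like germline (positions 1/3/4/66/79)
parental_vl_seq <- function() mutate_at(canonical_vl(), 66, "A")

numbered <- function(seq, chain = "L", id = "fixture") {
  assign_kabat_numbering(seq, chain, source_id = id)
}

table2_kinetics <- function() spr_kinetics_reference()

bi_profile <- function(times = c(1, 2, 4, 8, 24, 48, 72, 96, 120, 144),
                       C0a = 76.4, C0b = 45.1, t_half_alpha = 5,
                       t_half_beta = 96.3) {
  data.frame(
    time_h = times,
    conc_mg_per_L = C0a * exp(-log(2) / t_half_alpha * times) +
      C0b * exp(-log(2) / t_half_beta * times))
}
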