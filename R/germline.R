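#' Percent identity between two numbered sequences
#'
#' Identity is computed over Kabat positions present in both sequences within
#' the selected regions; positions absent from either sequence are excluded
#' from the denominator. `X` never counts as a match.
#'
#' @param a,b [numbered_seq()] objects on the same chain.
#' @param regions character vector of region names (`"FR1"`, `"CDR1"`, ...) or
#'   `"framework"` (FR1-FR3, the germline-comparison default) or `"all"`.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b, regions = "framework") {
  stopifnot(inherits(a, "numbered_seq"), inherits(b, "numbered_seq"))
  if (a$chain != b$chain) stop("sequences are on different chains")
  regions <- resolve_regions(regions)
  pa <- a$positions[a$positions$region %in% regions, ]
  pb <- b$positions[b$positions$region %in% regions, ]
  shared <- merge(pa[, c("label", "residue")], pb[, c("label", "residue")],
                  by = "label", suffixes = c("_a", "_b"))
  if (nrow(shared) == 0) stop("no overlapping positions in the selected regions")
  matches <- shared$residue_a == shared$residue_b &
    shared$residue_a != "X" & shared$residue_b != "X"
  100 * sum(matches) / nrow(shared)
}

resolve_regions <- function(regions) {
  all_regions <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
  if (identical(regions, "framework")) return(c("FR1", "FR2", "FR3"))
  if (identical(regions, "all")) return(all_regions)
  bad <- setdiff(regions, all_regions)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  regions
}

## Positions shared by query and germline within FR1-FR3 where the residues
## differ (X never matches).
framework_mismatches <- function(query, germline) {
  fr <- c("FR1", "FR2", "FR3")
  pq <- query$positions[query$positions$region %in% fr, ]
  pg <- germline$positions[germline$positions$region %in% fr, ]
  m <- merge(pq[, c("number", "ins", "label", "residue")],
             pg[, c("label", "residue")],
             by = "label", suffixes = c("_query", "_germline"))
  m <- m[m$residue_query != m$residue_germline |
           m$residue_query == "X" | m$residue_germline == "X", ]
  m <- m[order(m$number, m$ins), ]
  data.frame(number = m$number, ins = m$ins, label = m$label,
             query = m$residue_query, germline = m$residue_germline,
             stringsAsFactors = FALSE)
}

#' Find the closest germline V gene
#'
#' Scans a germline reference set and returns the gene with the highest
#' framework (FR1-FR3) identity to the query; ties are broken by total
#' V-region identity (all positions the germline covers), then by reference
#' order. Germline V genes end within CDR3, so FR4 never enters either score.
#'
#' @param query a [numbered_seq()] object.
#' @param reference named list of germline [numbered_seq()] objects, e.g. from
#'   [load_germline_reference()].
#' @return A `germline_match` list: `germline_id`, `framework_identity`,
#'   `total_identity`, and `mismatches` (FR1-FR3 positions where query and
#'   germline differ).
#' @export
find_closest_germline <- function(query, reference) {
  if (length(reference) == 0) stop("empty germline reference set")
  reference <- Filter(function(g) g$chain == query$chain, reference)
  if (length(reference) == 0) stop("no germline reference on chain ", query$chain)
  fw <- vapply(reference, function(g) percent_identity(query, g, "framework"),
               numeric(1))
  tot <- vapply(reference, function(g) percent_identity(query, g, "all"),
                numeric(1))
  best <- which(fw == max(fw))
  if (length(best) > 1) best <- best[which.max(tot[best])]
  best <- best[1]
  g <- reference[[best]]
  structure(list(
    germline_id = if (!is.null(names(reference))) names(reference)[best] else g$source_id,
    framework_identity = fw[[best]],
    total_identity = tot[[best]],
    mismatches = framework_mismatches(query, g),
    germline = g
  ), class = "germline_match")
}

#' @export
print.germline_match <- function(x, ...) {
  cat(sprintf("<germline_match> %s: framework %.2f%%, total V region %.2f%%, %d framework mismatch(es)\n",
              x$germline_id, x$framework_identity, x$total_identity,
              nrow(x$mismatches)))
  if (nrow(x$mismatches)) print(x$mismatches[, c("label", "query", "germline")])
  invisible(x)
}

#' Load the bundled synthetic germline reference set
#'
#' A small stand-in for a public germline V-gene database: six kappa VL genes
#' (including an IGKV3-20-like entry) and one VH3-23-like heavy gene,
#' constructed around the package's consensus templates. Sequences end within
#' CDR3, as germline V genes do.
#'
#' @param path optional FASTA path; defaults to the bundled set. Record ids
#'   ending in `|H` are numbered as heavy chain, all others as kappa light.
#' @return Named list of [numbered_seq()] objects.
#' @export
load_germline_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "germline_v_synthetic.fasta",
                        package = "abframe", mustWork = TRUE)
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    chain <- if (grepl("\\|H$", ids[i])) "H" else "L"
    assign_kabat_numbering(as.character(set[[i]]), chain, source_id = ids[i])
  })
  names(out) <- sub("\\|[LH]$", "", ids)
  out
}

#' Positional residue frequency profile
#'
#' Builds a per-position relative-frequency table from a reference set of
#' numbered sequences (the role a large curated framework-sequence database
#' plays when scoring how unusual a residue is at a position).
#'
#' @param seqs list of [numbered_seq()] objects on one chain.
#' @return A `frequency_profile`: named list mapping Kabat labels to residue
#'   frequency vectors, each summing to 1.
#' @export
frequency_profile <- function(seqs) {
  stopifnot(length(seqs) > 0)
  chain <- unique(vapply(seqs, function(s) s$chain, character(1)))
  if (length(chain) != 1) stop("all sequences must be on the same chain")
  all_pos <- do.call(rbind, lapply(seqs, function(s) s$positions[, c("label", "residue")]))
  tabs <- tapply(all_pos$residue, all_pos$label, function(r) {
    tt <- table(r)
    as.numeric(tt) / sum(tt) -> fr
    names(fr) <- names(tt)
    fr
  })
  structure(list(chain = chain, freq = as.list(tabs)), class = "frequency_profile")
}

#' Residue frequency at a Kabat position
#'
#' @param profile a [frequency_profile()].
#' @param pos Kabat position label, e.g. `"66"` or `"27a"`.
#' @param residue one-letter amino-acid code.
#' @return Relative frequency as a percent (0 for a residue never observed).
#' @export
positional_frequency <- function(profile, pos, residue) {
  stopifnot(inherits(profile, "frequency_profile"))
  pos <- as.character(pos)
  if (!pos %in% names(profile$freq)) stop("unknown position: ", pos)
  fr <- profile$freq[[pos]]
  100 * if (residue %in% names(fr)) unname(fr[residue]) else 0
}

#' Group framework mismatches into contiguous mutation regions
#'
#' Neighbouring mismatches merge into one region when at most one matching
#' position lies between them (Kabat numbers within 2 of the previous
#' mismatch); otherwise a new region starts. A parental framework differing
#' from its germline at Kabat 1, 3, 4, 66 and 79 therefore yields the three
#' regions 1-4 (position 2 matches but is bridged), 66 and 79.
#'
#' @param mismatches mismatch data frame from [find_closest_germline()]
#'   (columns `number`, `ins`, `label`, `query`, `germline`), sorted by
#'   position.
#' @return List of `mutation_region` lists: `label` (e.g. `"1-4"`, `"66"`),
#'   `numbers`, `labels`, `parental`, `germline`.
#' @export
group_mismatches <- function(mismatches) {
  if (nrow(mismatches) == 0) return(list())
  if (is.unsorted(mismatches$number)) stop("mismatches must be sorted by position")
  brk <- cumsum(c(1, diff(mismatches$number) > 2))
  lapply(split(mismatches, brk), function(m) {
    lab <- if (min(m$number) == max(m$number)) as.character(m$number[1]) else
      paste0(min(m$number), "-", max(m$number))
    structure(list(label = lab,
                   numbers = m$number, labels = m$label,
                   parental = m$query, germline = m$germline),
              class = "mutation_region")
  }) |> unname()
}

region_signature_labels <- function(region) {
  ## the signature spans the full residue range of the region (a 1-4 region
  ## contributes four letters even if an interior position already matches)
  as.character(seq.int(min(region$numbers), max(region$numbers)))
}

apply_region_choice <- function(positions, region) {
  idx <- match(region$labels, positions$label)
  if (anyNA(idx)) stop("region position absent from parental sequence")
  positions$residue[idx] <- region$germline
  positions
}

#' Enumerate combinatorial germlining variants
#'
#' Builds every parental/germline combination over the mutation regions
#' (2^k sequences) and names each variant by the concatenated residues at the
#' signature positions, the scheme used for the BaxM159 panel (a 1-4 region
#' contributes four letters, single positions one each). Variants are ordered
#' by the number of germlined regions, then lexicographically by region
#' combination, with the all-parental variant first; when
#' `include_lysine_parental` is set, a duplicate of the parental carrying the
#' heavy-chain C-terminal lysine is inserted as the second entry with a `-K`
#' name suffix.
#'
#' @param parental parental VL as a [numbered_seq()].
#' @param regions list of mutation regions from [group_mismatches()].
#' @param include_lysine_parental add the `-K` parental duplicate.
#' @return A `variant_panel`: data frame with columns `id`, `name`,
#'   `c_terminal_lysine`, `n_germline`, `choices` (e.g. `"P/G/P"`), `sequence`,
#'   plus the regions as an attribute.
#' @export
enumerate_variants <- function(parental, regions, include_lysine_parental = FALSE) {
  k <- length(regions)
  if (k < 1) stop("at least one mutation region is required")
  if (k > 12) stop("combinatorial limit: more than 12 mutation regions")
  sig_labels <- unlist(lapply(regions, region_signature_labels))
  combos <- list(integer(0))
  for (m in seq_len(k)) {
    cmb <- utils::combn(k, m)
    combos <- c(combos, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  rows <- lapply(combos, function(idx) {
    pos <- parental$positions
    for (i in idx) pos <- apply_region_choice(pos, regions[[i]])
    sig <- pos$residue[match(sig_labels, pos$label)]
    if (anyNA(sig)) stop("signature position absent from parental sequence")
    list(name = paste(sig, collapse = ""),
         choices = paste(ifelse(seq_len(k) %in% idx, "G", "P"), collapse = "/"),
         n_germline = length(idx),
         sequence = paste(pos$residue, collapse = ""))
  })
  panel <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r$name, c_terminal_lysine = FALSE,
               n_germline = r$n_germline, choices = r$choices,
               sequence = r$sequence, stringsAsFactors = FALSE)
  }))
  if (include_lysine_parental) {
    lys <- panel[1, ]
    lys$name <- paste0(lys$name, "-K")
    lys$c_terminal_lysine <- TRUE
    panel <- rbind(panel[1, ], lys, panel[-1, ])
  }
  panel <- cbind(id = seq_len(nrow(panel)), panel)
  rownames(panel) <- NULL
  if (anyDuplicated(panel$name)) stop("variant names are not unique")
  structure(panel, class = c("variant_panel", "data.frame"),
            regions = regions, parental_id = parental$source_id)
}

#' Write a variant panel to FASTA and a summary table
#'
#' @param panel a [enumerate_variants()] panel.
#' @param fasta,table output paths (either may be `NULL` to skip).
#' @return The panel, invisibly.
#' @export
write_variant_panel <- function(panel, fasta = NULL, table = NULL) {
  if (!is.null(fasta)) {
    set <- Biostrings::AAStringSet(panel$sequence)
    names(set) <- sprintf("%d-%s", panel$id, panel$name)
    Biostrings::writeXStringSet(set, fasta)
  }
  if (!is.null(table)) {
    utils::write.table(panel[, c("id", "name", "choices", "c_terminal_lysine")],
                       table, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(panel)
}
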