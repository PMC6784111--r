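#' @useDynLib abframe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET20X <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                    "R","S","T","V","W","Y","X")

## Kabat region spans per chain. Light (kappa) and heavy V-domain numbering
## ranges; spans partition the plain (insertion-free) numbering range.
KABAT_REGIONS <- list(
  L = data.frame(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    from   = c(1, 24, 35, 50, 57, 89, 98),
    to     = c(23, 34, 49, 56, 88, 97, 107),
    stringsAsFactors = FALSE
  ),
  H = data.frame(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    from   = c(1, 31, 36, 50, 66, 95, 103),
    to     = c(30, 35, 49, 65, 94, 102, 113),
    stringsAsFactors = FALSE
  )
)

## Canonical insertion sites: insertion letters are appended after these
## numbers, up to the stated maximum count.
KABAT_INSERTION_SITES <- list(
  L = data.frame(site = c(27L, 95L, 106L), max_ins = c(6L, 6L, 1L)),
  H = data.frame(site = c(35L, 52L, 82L, 100L), max_ins = c(2L, 3L, 3L, 11L))
)

## Synthetic per-chain consensus templates with plain 1..107 (L, kappa) and
## 1..113 (H) numbering; the anchor for alignment-based number assignment.
KABAT_TEMPLATES <- list(
  L = paste0(
    "DIQMTQSPSSLSASVGDRVTITC",            # FR1  1-23
    "RASQSISSYLN",                        # CDR1 24-34
    "WYQQKPGKAPKLLIY",                    # FR2  35-49
    "AASSLQS",                            # CDR2 50-56
    "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC",   # FR3  57-88
    "QQSYSTPLT",                          # CDR3 89-97
    "FGQGTKVEIK"                          # FR4  98-107
  ),
  H = paste0(
    "EVQLLESGGGLVQPGGSLRLSCAASGFTFS",     # FR1  1-30
    "SYAMS",                              # CDR1 31-35
    "WVRQAPGKGLEWVS",                     # FR2  36-49
    "AISGSGGSTYYADSVK",                   # CDR2 50-65
    "GRFTISRDNSKNTLYLQMNSLRAEDTAVY",      # FR3  66-94
    "DRGYGMDY",                           # CDR3 95-102
    "WGQGTLVTVSS"                         # FR4  103-113
  )
)

kabat_region_of <- function(chain, number) {
  spans <- KABAT_REGIONS[[chain]]
  idx <- findInterval(number, spans$from)
  out <- rep(NA_character_, length(number))
  ok <- idx >= 1 & number <= spans$to[pmax(idx, 1)]
  out[ok] <- spans$region[idx[ok]]
  out
}

kabat_label <- function(number, ins = "") paste0(number, ins)

#' Construct a numbered V-domain sequence
#'
#' Low-level constructor used by [assign_kabat_numbering()]. Positions must be
#' supplied in strictly increasing Kabat order (number, then insertion letter).
#'
#' @param chain `"L"` or `"H"`.
#' @param number integer Kabat numbers.
#' @param ins insertion codes (`""` or a lowercase letter).
#' @param residue one-letter amino-acid codes (20 letters plus `X`).
#' @param source_id identifier carried through reports.
#' @return An object of class `numbered_seq`: a list with elements `chain`,
#'   `source_id` and a `positions` data frame (`number`, `ins`, `label`,
#'   `region`, `residue`).
#' @export
numbered_seq <- function(chain, number, ins, residue, source_id = "") {
  chain <- match.arg(chain, c("L", "H"))
  stopifnot(length(number) == length(ins), length(number) == length(residue))
  if (!all(residue %in% AA_ALPHABET20X)) {
    stop("residues must be one-letter amino-acid codes (20 letters plus X)")
  }
  ord <- order(number, ins)
  if (any(ord != seq_along(number))) {
    stop("Kabat positions must be strictly increasing")
  }
  key <- paste0(number, ins)
  if (anyDuplicated(key)) stop("duplicate Kabat positions")
  pos <- data.frame(
    number = as.integer(number),
    ins = ins,
    label = kabat_label(number, ins),
    region = kabat_region_of(chain, as.integer(number)),
    residue = residue,
    stringsAsFactors = FALSE
  )
  if (anyNA(pos$region)) stop("Kabat number outside the numbering range")
  structure(list(chain = chain, source_id = source_id, positions = pos),
            class = "numbered_seq")
}

#' @export
print.numbered_seq <- function(x, ...) {
  cat(sprintf("<numbered_seq> chain %s, %d residues (%s)\n",
              x$chain, nrow(x$positions),
              if (nzchar(x$source_id)) x$source_id else "unnamed"))
  reg <- delineate_regions(x)
  for (r in names(reg)) cat(sprintf("  %-5s %s\n", r, reg[[r]]))
  invisible(x)
}

#' @export
as.character.numbered_seq <- function(x, ...) paste(x$positions$residue, collapse = "")

validate_aa_sequence <- function(sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, AA_ALPHABET20X)
  if (length(bad) > 0) {
    stop(sprintf("input error: non-amino-acid character(s): %s",
                 paste(unique(bad), collapse = ", ")))
  }
  sequence
}

## Split an aligned query/template pair into per-region query fragments plus
## the template positions each matched query residue sits on. Insertion runs
## (gaps in the template) are attached to the adjacent CDR when they border
## one, otherwise to the region of the preceding template position.
collect_alignment_regions <- function(p_chars, s_chars, tmpl_offset, chain) {
  spans <- KABAT_REGIONS[[chain]]
  n_col <- length(p_chars)
  tmpl_pos <- integer(n_col)   # template (= plain Kabat) number per column, 0 for gap
  k <- tmpl_offset - 1L
  for (i in seq_len(n_col)) {
    if (s_chars[i] != "-") k <- k + 1L
    tmpl_pos[i] <- if (s_chars[i] != "-") k else 0L
  }
  col_region <- rep(NA_character_, n_col)
  col_region[tmpl_pos > 0] <- kabat_region_of(chain, tmpl_pos[tmpl_pos > 0])
  # assign insertion columns (template gaps)
  for (i in which(tmpl_pos == 0L)) {
    left <- if (any(tmpl_pos[seq_len(i - 1)] > 0)) {
      max(which(tmpl_pos[seq_len(i - 1)] > 0))
    } else 0L
    right_candidates <- which(tmpl_pos > 0 & seq_len(n_col) > i)
    right <- if (length(right_candidates)) min(right_candidates) else 0L
    lr <- if (left > 0) col_region[left] else NA_character_
    rr <- if (right > 0) col_region[right] else NA_character_
    pick <- if (!is.na(lr) && grepl("CDR", lr)) lr
            else if (!is.na(rr) && grepl("CDR", rr)) rr
            else if (!is.na(lr)) lr
            else rr
    if (is.na(pick)) {
      stop(sprintf("numbering error (chain %s): insertion outside the numbering range", chain))
    }
    col_region[i] <- pick
  }
  out <- list()
  for (r in spans$region) {
    cols <- which(col_region == r & p_chars != "-")
    out[[r]] <- list(residues = p_chars[cols], tmpl_numbers = tmpl_pos[cols])
  }
  out
}

## Renumber one region's residues onto Kabat positions. Regions without length
## deviation (or with deletions only) keep the alignment's own mapping; length
## excess is forced onto the chain's canonical insertion site for that region.
number_region <- function(chain, region, residues, tmpl_numbers) {
  spans <- KABAT_REGIONS[[chain]]
  row <- spans[spans$region == region, ]
  span <- seq.int(row$from, row$to)
  L <- length(residues)
  L0 <- length(span)
  sites <- KABAT_INSERTION_SITES[[chain]]
  site_row <- sites[sites$site >= row$from & sites$site <= row$to, , drop = FALSE]
  n_ins <- sum(tmpl_numbers == 0L)
  if (n_ins == 0L) {
    # direct mapping; template gaps simply leave positions absent
    return(data.frame(number = tmpl_numbers, ins = "", residue = residues,
                      stringsAsFactors = FALSE))
  }
  if (nrow(site_row) == 0L) {
    stop(sprintf(
      "numbering error (chain %s): insertion in %s, which has no canonical insertion site",
      chain, region))
  }
  s <- site_row$site[1]
  if (L <= L0) {
    # insertions and deletions cancel; renumber against the span with the
    # deficit taken from the omission order around the site
    d <- L0 - L
    omit_order <- c(span[span > s], s, rev(span[span < s]))
    keep <- sort(setdiff(span, omit_order[seq_len(d)]))
    return(data.frame(number = keep, ins = "", residue = residues,
                      stringsAsFactors = FALSE))
  }
  extra <- L - L0
  if (extra > site_row$max_ins[1]) {
    stop(sprintf(
      "numbering error (chain %s): %d insertions exceed the %s capacity at site %d",
      chain, extra, region, s))
  }
  pre <- span[span <= s]
  post <- span[span > s]
  number <- c(pre, rep(s, extra), post)
  ins <- c(rep("", length(pre)), letters[seq_len(extra)], rep("", length(post)))
  data.frame(number = number, ins = ins, residue = residues,
             stringsAsFactors = FALSE)
}

#' Assign Kabat numbers to a V-domain amino-acid sequence
#'
#' Aligns the query globally against a bundled per-chain consensus template
#' (BLOSUM62, affine gaps) and maps each residue to a Kabat position. Length
#' variation relative to the template is renumbered region by region:
#' insertions receive letter codes at the chain's canonical insertion sites
#' (L: 27a-f, 95a-f, 106a; H: 35a-b, 52a-c, 82a-c, 100a-k) and deletions leave
#' positions absent, taken from a fixed omission order around the site.
#'
#' @param sequence V-domain amino-acid sequence (80-140 residues, one-letter
#'   codes; `X` permitted).
#' @param chain `"L"` (kappa light) or `"H"` (heavy).
#' @param source_id identifier carried into reports.
#' @param min_identity minimum fraction of identical residues against the
#'   chain consensus below which numbering is refused (default 0.4).
#' @return A [numbered_seq()] object.
#' @examples
#' vl <- assign_kabat_numbering(kabat_template("L"), chain = "L")
#' head(vl$positions)
#' @export
assign_kabat_numbering <- function(sequence, chain = c("L", "H"),
                                   source_id = "", min_identity = 0.4) {
  chain <- match.arg(chain)
  sequence <- validate_aa_sequence(sequence)
  n <- nchar(sequence)
  if (n < 80 || n > 140) {
    stop(sprintf("numbering error (chain %s): sequence length %d outside 80-140",
                 chain, n))
  }
  tmpl <- KABAT_TEMPLATES[[chain]]
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(sequence),
    subject = Biostrings::AAString(tmpl),
    substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5,
    type = "global-local"
  )
  p_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(p_chars == s_chars & p_chars != "-") / n
  if (ident < min_identity) {
    stop(sprintf(
      "numbering error (chain %s): identity to chain consensus %.0f%% < %.0f%%",
      chain, 100 * ident, 100 * min_identity))
  }
  tmpl_offset <- Biostrings::start(Biostrings::subject(aln))
  regs <- collect_alignment_regions(p_chars, s_chars, tmpl_offset, chain)
  parts <- lapply(names(regs), function(r) {
    if (length(regs[[r]]$residues) == 0) return(NULL)
    number_region(chain, r, regs[[r]]$residues, regs[[r]]$tmpl_numbers)
  })
  pos <- do.call(rbind, parts)
  numbered_seq(chain, pos$number, pos$ins, pos$residue, source_id = source_id)
}

#' Bundled Kabat consensus template
#'
#' @param chain `"L"` or `"H"`.
#' @return The consensus amino-acid string used as the numbering anchor
#'   (plain 1-107 for L, 1-113 for H).
#' @export
kabat_template <- function(chain = c("L", "H")) {
  KABAT_TEMPLATES[[match.arg(chain)]]
}

#' Split a numbered sequence into framework and CDR regions
#'
#' @param ns a [numbered_seq()] object.
#' @return Named list of residue strings in the order FR1, CDR1, FR2, CDR2,
#'   FR3, CDR3, FR4 (regions with no residues are returned as `""`).
#'   Concatenating the elements reproduces the input sequence.
#' @export
delineate_regions <- function(ns) {
  stopifnot(inherits(ns, "numbered_seq"))
  spans <- KABAT_REGIONS[[ns$chain]]
  out <- lapply(spans$region, function(r) {
    paste(ns$positions$residue[ns$positions$region == r], collapse = "")
  })
  names(out) <- spans$region
  out
}

#' Framework concatenation FR1+FR2+FR3
#'
#' Convenience accessor for the germline-comparison denominator (70 positions
#' for an insertion-free kappa VL).
#'
#' @param ns a [numbered_seq()] object.
#' @return Residue string over FR1-FR3.
#' @export
framework_sequence <- function(ns) {
  reg <- delineate_regions(ns)
  paste0(reg$FR1, reg$FR2, reg$FR3)
}

#' Read V-domain sequences from FASTA
#'
#' @param path FASTA file (single or multi-record).
#' @param chain chain assumed for every record.
#' @return List of [numbered_seq()] objects named by FASTA record id.
#' @export
read_v_fasta <- function(path, chain = c("L", "H")) {
  chain <- match.arg(chain)
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    assign_kabat_numbering(as.character(set[[i]]), chain, source_id = ids[i])
  })
  names(out) <- ids
  out
}

#' Write a numbered sequence as a two-column table
#'
#' @param ns a [numbered_seq()] object.
#' @param path output path; a tab-delimited table with columns
#'   `kabat_position` and `residue`.
#' @return The table, invisibly.
#' @export
write_numbering_table <- function(ns, path) {
  tab <- data.frame(kabat_position = paste0(ns$chain, ns$positions$label),
                    residue = ns$positions$residue)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
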