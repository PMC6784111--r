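#' Generator configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-data generators with the study's
#' default conditions: a kappa VL panel with five planted framework mismatches
#' in three groupable regions, SPR at five analyte concentrations within
#' 3-25 nM with 0.5 RU noise, DSF noise at 1% of the transition amplitude,
#' SEC noise at 0.5% of the peak maximum, lognormal titer replicates at 20%
#' CV, and an intravenous PK design at 5/15/30 mg/kg with n = 4 animals,
#' 3% multiplicative noise, sampling at {1,2,4,8,24,48,72,96,120,144} h and a
#' 0.15 mg/L limit of quantification.
#'
#' @param seed integer seed fixing every downstream draw.
#' @param planted_mutations named character vector: Kabat label -> parental
#'   residue planted as a framework deviation from the closest germline.
#' @param include_lysine_parental add the `-K` parental duplicate to the panel.
#' @param ... overrides for individual fields (see defaults in the returned
#'   list: `spr`, `dsf`, `sec`, `titer`, `pk`).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             planted_mutations = c("1" = "D", "3" = "Q",
                                                   "4" = "M", "66" = "A",
                                                   "79" = "Q"),
                             include_lysine_parental = TRUE, ...) {
  cfg <- list(
    seed = as.integer(seed),
    planted_mutations = planted_mutations,
    include_lysine_parental = include_lysine_parental,
    spr = list(concentrations = c(3.125, 6.25, 12.5, 18.75, 25) * 1e-9,
               times = seq(0, 600, by = 5), t_stop = 300, noise_sd = 0.5,
               parental_ka = 1.1e5, parental_kd = 2.9e-4,
               ka_range = c(1.3e5, 3.1e5), kd_range = c(2.9e-4, 6.4e-4)),
    dsf = list(tm_parental = 70, slope = 1.5, amplitude = 5000,
               pre = c(1000, 2), grid = seq(25, 95, by = 0.5),
               noise_frac = 0.01),
    sec = list(retention = c(aggregate = 6.0, dimer = 7.2, monomer = 8.6,
                             fragment = 11.0),
               widths = 0.12, weeks = c(0, 2, 4, 8, 12),
               total_area = 100, noise_frac = 0.005,
               monomer_parental = 0.89, monomer_optimized = 0.975,
               decline_parental = 0.04, decline_optimized = 0.02),
    titer = list(parental_mean = 120, cv = 0.20, replicates = 5),
    pk = list(doses = c(5, 15, 30),
              times = c(1, 2, 4, 8, 24, 48, 72, 96, 120, 144),
              n_animals = 4, cv = 0.03, loq = 0.15,
              t_half_alpha = 5, body_weight_kg = 0.030)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "generator_config")
}

## full-length kappa VL built on the closest-germline framework: the bundled
## IGKV3-20-like gene extended through FR4, with the parental antibody's CDR
## residues (somatic) at the template positions
parental_backbone <- function() {
  tmpl <- strsplit(KABAT_TEMPLATES$L, "")[[1]]
  # germline framework residues at 1/3/4, 79 (EIVL / E79); template already
  # carries G66, so the backbone matches the germline over FR1-FR3
  tmpl[1] <- "E"; tmpl[3] <- "V"; tmpl[4] <- "L"; tmpl[79] <- "E"
  tmpl
}

#' Generate the synthetic germlining study panel
#'
#' Builds a parental kappa VL by planting the configured framework mismatches
#' onto the closest bundled germline's framework, scans the germline reference,
#' groups the mismatches into mutation regions and enumerates the
#' combinatorial variant panel (the default five planted mismatches form three
#' regions and the panel has 2^3 + 1 = 9 entries including the lysine-bearing
#' parental duplicate).
#'
#' @param config a [generator_config()].
#' @return List: `parental` ([numbered_seq()]), `germline_match`, `regions`,
#'   `panel` ([enumerate_variants()] panel, or a single-row panel when no
#'   mismatch was planted).
#' @export
generate_variant_panel <- function(config = generator_config()) {
  backbone <- parental_backbone()
  planted <- config$planted_mutations
  for (lab in names(planted)) {
    i <- as.integer(lab)
    if (is.na(i) || i < 1 || i > length(backbone)) stop("planted position outside the VL: ", lab)
    backbone[i] <- planted[[lab]]
  }
  parental <- assign_kabat_numbering(paste(backbone, collapse = ""), "L",
                                     source_id = "parental-VL")
  germs <- load_germline_reference()
  match <- find_closest_germline(parental, germs)
  regions <- group_mismatches(match$mismatches)
  if (length(regions) == 0) {
    panel <- data.frame(id = 1L, name = "parental", c_terminal_lysine = FALSE,
                        n_germline = 0L, choices = "",
                        sequence = as.character(parental))
    panel <- structure(panel, class = c("variant_panel", "data.frame"),
                       regions = list(), parental_id = parental$source_id)
  } else {
    panel <- enumerate_variants(parental, regions,
                                include_lysine_parental = config$include_lysine_parental)
  }
  list(parental = parental, germline_match = match, regions = regions,
       panel = panel)
}

## Tm offsets keyed to region content for the default three-region panel
## (regions ordered 1-4, 66, 79): combining the 1-4 and 66 germline choices is
## synergistic; the 79 choice alone carries the largest single-region shift.
tm_offset_rule <- function(choices_list) {
  vapply(choices_list, function(ch) {
    g <- ch == "G"
    if (length(g) != 3) return(0.7 * sum(g))
    if (g[1] && g[2]) 4.1 + 0.2 * g[3]
    else if (g[3]) 2.2 + 0.1 * (g[1] + g[2])
    else if (g[1] || g[2]) 0.5 + 0.1 * g[2]
    else 0
  }, numeric(1))
}

## titer fold-effects: the position-66 glycine reversion drives expression
## (3-5 fold alone, 4-10 fold in combination); everything else is neutral.
titer_fold_rule <- function(choices_list) {
  vapply(choices_list, function(ch) {
    g <- ch == "G"
    has66 <- length(g) >= 2 && g[2]
    if (has66 && sum(g) == 1) stats::runif(1, 3, 5)
    else if (has66) stats::runif(1, 4, 10)
    else stats::runif(1, 0.9, 1.3)
  }, numeric(1))
}

#' Generate the synthetic assay suite for a variant panel
#'
#' Draws a per-variant truth table mirroring the study's effect sizes (ka and
#' kd inside 1.3-3.1e5 / 2.9-6.4e-4 with every KD within a factor of two of
#' the parental truth; Tm offsets of about 0, +0.5, +2 and +4 deg C keyed to
#' region content; 3-10x titer folds for variants carrying the position-66
#' glycine; monomer fractions of about 0.975 for the fully germlined variant
#' vs 0.89 for the parental, declining slowly over 12 weeks) and simulates
#' sensorgrams, melt curves, titer replicates and SEC stability time courses
#' from it.
#'
#' @param config a [generator_config()].
#' @param panel result of [generate_variant_panel()].
#' @return List: `truth` (data frame), `sensorgrams`, `melt_curves`, `titers`
#'   (replicate vectors), `timecourses` (parental and fully germlined
#'   variant), all named by variant.
#' @export
generate_assay_suite <- function(config, panel) {
  stopifnot(nrow(panel$panel) >= 1)
  set.seed(config$seed)
  pan <- panel$panel
  nm <- pan$name
  choices_list <- lapply(strsplit(pan$choices, "/"), identity)
  kd_p <- config$spr$parental_kd; ka_p <- config$spr$parental_ka
  KD_p <- kd_p / ka_p
  ka <- kd <- numeric(nrow(pan))
  for (i in seq_len(nrow(pan))) {
    if (pan$n_germline[i] == 0) {        # parental (and its -K duplicate)
      ka[i] <- ka_p; kd[i] <- kd_p
    } else {
      kdlo <- max(config$spr$kd_range[1] / config$spr$ka_range[2], KD_p / 2)
      kdhi <- min(config$spr$kd_range[2] / config$spr$ka_range[1], KD_p * 2)
      KD_i <- stats::runif(1, kdlo, kdhi)
      alo <- max(config$spr$ka_range[1], config$spr$kd_range[1] / KD_i)
      ahi <- min(config$spr$ka_range[2], config$spr$kd_range[2] / KD_i)
      ka[i] <- stats::runif(1, alo, ahi)
      kd[i] <- KD_i * ka[i]
    }
  }
  tm <- config$dsf$tm_parental + tm_offset_rule(choices_list)
  fold <- titer_fold_rule(choices_list)
  fold[pan$n_germline == 0] <- 1
  titer_mean <- config$titer$parental_mean * fold
  kmax <- max(pan$n_germline)
  mono0 <- config$sec$monomer_parental +
    (config$sec$monomer_optimized - config$sec$monomer_parental) *
    (if (kmax > 0) pan$n_germline / kmax else 0)
  truth <- data.frame(name = nm, ka = ka, kd = kd, KD = kd / ka, tm = tm,
                      titer_fold = fold, titer_mean = titer_mean,
                      monomer0 = mono0, stringsAsFactors = FALSE)

  sensorgrams <- lapply(seq_len(nrow(pan)), function(i) {
    simulate_sensorgram(ka[i], kd[i], Rmax = 60,
                        concentrations = config$spr$concentrations,
                        times = config$spr$times, t_stop = config$spr$t_stop,
                        noise_sd = config$spr$noise_sd)
  })
  melt_curves <- lapply(seq_len(nrow(pan)), function(i) {
    simulate_melt_curve(tm[i], slope = config$dsf$slope,
                        pre = config$dsf$pre,
                        post = c(config$dsf$pre[1] + config$dsf$amplitude,
                                 config$dsf$pre[2]),
                        grid = config$dsf$grid,
                        noise_sd = config$dsf$noise_frac * config$dsf$amplitude)
  })
  sdlog <- sqrt(log(1 + config$titer$cv^2))
  titers <- lapply(seq_len(nrow(pan)), function(i) {
    stats::rlnorm(config$titer$replicates,
                  meanlog = log(titer_mean[i]) - sdlog^2 / 2, sdlog = sdlog)
  })
  names(sensorgrams) <- names(melt_curves) <- names(titers) <- nm

  tc_variants <- unique(c(nm[1], nm[which.max(pan$n_germline)]))
  timecourses <- lapply(tc_variants, function(v) {
    i <- match(v, nm)
    decline <- if (pan$n_germline[i] == kmax && kmax > 0)
      config$sec$decline_optimized else config$sec$decline_parental
    weeks <- config$sec$weeks
    tabs <- lapply(weeks, function(w) {
      m <- mono0[i] - decline * w / max(weeks)
      lost <- mono0[i] - m
      fr <- c(aggregate = (1 - mono0[i]) * 0.25 + lost * 0.45,
              dimer = (1 - mono0[i]) * 0.45 + lost * 0.45,
              monomer = m,
              fragment = (1 - mono0[i]) * 0.30 + lost * 0.10)
      tr <- simulate_chromatogram(
        areas = fr * config$sec$total_area,
        retention = config$sec$retention, widths = config$sec$widths,
        noise_sd = config$sec$noise_frac * max(fr) * config$sec$total_area /
          (config$sec$widths * sqrt(2 * pi)))
      quantify_species(tr, sec_default_windows(config$sec$retention))
    })
    list(weeks = weeks, tables = tabs)
  })
  names(timecourses) <- tc_variants

  list(truth = truth, sensorgrams = sensorgrams, melt_curves = melt_curves,
       titers = titers, timecourses = timecourses)
}

#' Published SPR kinetic constants for the variant panel
#'
#' The surface plasmon resonance rate constants and equilibrium dissociation
#' constants reported for the nine BaxM159 VL framework variants.
#'
#' @return Data frame: `id`, `name`, `ka_per_M_s`, `kd_per_s`, `KD_M`.
#' @export
spr_kinetics_reference <- function() {
  utils::read.csv(system.file("extdata", "reference_spr_kinetics.csv",
                              package = "abframe", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published pharmacokinetic parameters for the in vivo study
#'
#' Two-compartment parameter estimates for the parental antibody
#' (2-DIQMAQ-K) and the fully germlined variant (9-EIVLGE) at 5, 15 and
#' 30 mg/kg intravenous doses in nude mice. The parental 5 mg/kg arm was below
#' the limit of quantification beyond 48 h, so its parameters are `NA`.
#'
#' @return Data frame: `antibody`, `dose_mg_per_kg`, `C0a_mg_per_L`,
#'   `C0b_mg_per_L`, `t_half_beta_h`, `AUC_0_144_mg_h_per_L`, `CL_mL_h_kg`,
#'   `VDss_mL_kg`.
#' @export
pk_reference <- function() {
  utils::read.csv(system.file("extdata", "reference_pk_parameters.csv",
                              package = "abframe", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

## Generating truths per PK arm: the published two-compartment parameters,
## plus an imputed mono-exponential curve for the parental 5 mg/kg arm whose
## parameters could not be determined (dose-scaled C0, accelerated terminal
## decay so the reported censoring pattern is reproducible under one LOQ).
pk_truth_table <- function(config) {
  ref <- pk_reference()
  ref$model <- "bi"
  ref$t_half_alpha_h <- config$pk$t_half_alpha
  ref$imputed <- FALSE
  na_row <- which(is.na(ref$C0a_mg_per_L))
  for (i in na_row) {
    donor <- ref[ref$antibody == ref$antibody[i] & !is.na(ref$C0a_mg_per_L), ][1, ]
    scale <- ref$dose_mg_per_kg[i] / donor$dose_mg_per_kg
    ref$model[i] <- "mono"
    ref$C0a_mg_per_L[i] <- 0
    ref$C0b_mg_per_L[i] <- (donor$C0a_mg_per_L + donor$C0b_mg_per_L) * scale
    ref$t_half_beta_h[i] <- 12
    ref$imputed[i] <- TRUE
  }
  ref
}

pk_true_conc <- function(truth_row, t) {
  beta <- log(2) / truth_row$t_half_beta_h
  if (truth_row$model == "mono") {
    truth_row$C0b_mg_per_L * exp(-beta * t)
  } else {
    alpha <- log(2) / truth_row$t_half_alpha_h
    truth_row$C0a_mg_per_L * exp(-alpha * t) +
      truth_row$C0b_mg_per_L * exp(-beta * t)
  }
}

#' Generate the synthetic intravenous PK study
#'
#' One dataset per antibody x dose, simulated from the published
#' two-compartment parameters (distribution half-life defaulting to 5 h, which
#' the study does not print) with multiplicative lognormal noise across n = 4
#' animals and LOQ censoring; the parental low-dose arm uses an imputed
#' mono-exponential truth and its tail falls below the LOQ beyond 48 h.
#'
#' @param config a [generator_config()].
#' @return Named list (`"antibody @ dose"`) of [pk_dataset()] objects, each
#'   carrying its generating `truth` row as an attribute; the truth table is
#'   attached to the list as attribute `truth`.
#' @export
generate_pk_study <- function(config = generator_config()) {
  set.seed(config$seed + 1L)
  truth <- pk_truth_table(config)
  truth <- truth[truth$dose_mg_per_kg %in% config$pk$doses, ]
  sdlog <- sqrt(log(1 + config$pk$cv^2))
  arms <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    tt <- rep(config$pk$times, times = config$pk$n_animals)
    ids <- rep(seq_len(config$pk$n_animals), each = length(config$pk$times))
    mu <- pk_true_conc(tr, tt)
    conc <- mu * stats::rlnorm(length(tt), -sdlog^2 / 2, sdlog)
    d <- pk_dataset(antibody = tr$antibody, dose = tr$dose_mg_per_kg,
                    time_h = tt, conc_mg_per_L = conc, animal_id = ids,
                    body_weight_kg = config$pk$body_weight_kg,
                    loq = config$pk$loq)
    attr(d, "truth") <- tr
    d
  })
  names(arms) <- sprintf("%s @ %g mg/kg", truth$antibody, truth$dose_mg_per_kg)
  structure(arms, truth = truth)
}
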