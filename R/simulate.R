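#' Simulation configuration for a synthetic MRM glycoproteomics cohort
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' study design the pipeline targets: 56 healthy controls, 23 NASH and 19 HCC
#' sera, a panel of 413 glycopeptides over 57 of 73 monitored serum
#' glycoproteins (each protein also contributing one non-glycosylated
#' peptide marker), a reference serum pool injected at every 10th position of
#' a randomized injection sequence, smooth multiplicative within-run drift,
#' log-normal biological and technical variation, and phenotype-linked
#' abundance shifts that concentrate in fucosylated/sialylated glycoforms.
#'
#' @param seed integer seed; mandatory, every downstream artifact must be
#'   reproducible from it.
#' @param n_control,n_nash,n_hcc study-arm sizes.
#' @param n_proteins number of monitored serum glycoproteins.
#' @param n_glycoproteins how many of those carry glycopeptide markers.
#' @param n_glycopeptides total glycopeptide markers in the panel.
#' @param qc_interval reference-pool spacing: every \code{qc_interval}-th
#'   injection is a pool (must be >= 2).
#' @param drift_amplitude fractional signal loss across the whole run; the
#'   drift trend decays smoothly from 1 to \code{1 - drift_amplitude}.
#' @param drift_jitter standard deviation of per-marker lognormal jitter
#'   multiplying the shared drift trend (0 = drift identical for all markers).
#' @param biological_cv coefficient of variation of the per-sample biological
#'   lognormal component.
#' @param technical_cv coefficient of variation of the per-injection
#'   technical lognormal component (also the only noise on pool injections).
#' @param effect_nash_up,effect_hcc_up log2 effects (vs control) applied to
#'   fucosylated AND sialylated glycoforms; HCC >= NASH by default so the
#'   progression cascade control < NASH < HCC is part of the ground truth.
#' @param effect_nash_down,effect_hcc_down log2 effects applied to
#'   non-fucosylated glycoforms carrying >= 2 sialic acids (negative).
#' @param age_effect_log2 log2 change per year of age (all markers).
#' @param sex_effect_log2 log2 male-vs-female offset (all markers).
#' @param effect_table optional data frame (\code{marker_id},
#'   \code{contrast} in \code{"NASH"}/\code{"HCC"}, \code{log2fc})
#'   overriding the motif-derived effects for the listed markers.
#' @param missing_rate fraction of study-sample cells set to NA (default 0;
#'   the pipeline assumes complete data).
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed,
                       n_control = 56L, n_nash = 23L, n_hcc = 19L,
                       n_proteins = 73L, n_glycoproteins = 57L,
                       n_glycopeptides = 413L,
                       qc_interval = 10L,
                       drift_amplitude = 0.2, drift_jitter = 0,
                       biological_cv = 0.30, technical_cv = 0.05,
                       effect_nash_up = 0.5, effect_hcc_up = 0.8,
                       effect_nash_down = -0.35, effect_hcc_down = -0.55,
                       age_effect_log2 = 0.002, sex_effect_log2 = 0.05,
                       effect_table = NULL,
                       missing_rate = 0) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is required: simulated cohorts must be reproducible")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_control = as.integer(n_control), n_nash = as.integer(n_nash),
    n_hcc = as.integer(n_hcc),
    n_proteins = as.integer(n_proteins),
    n_glycoproteins = as.integer(n_glycoproteins),
    n_glycopeptides = as.integer(n_glycopeptides),
    qc_interval = as.integer(qc_interval),
    drift_amplitude = drift_amplitude, drift_jitter = drift_jitter,
    biological_cv = biological_cv, technical_cv = technical_cv,
    effect_nash_up = effect_nash_up, effect_hcc_up = effect_hcc_up,
    effect_nash_down = effect_nash_down, effect_hcc_down = effect_hcc_down,
    age_effect_log2 = age_effect_log2, sex_effect_log2 = sex_effect_log2,
    effect_table = effect_table, missing_rate = missing_rate
  )
  if (cfg$qc_interval < 2L) stop("qc_interval must be >= 2")
  if (any(c(cfg$n_control, cfg$n_nash, cfg$n_hcc) < 2L)) {
    stop("each phenotype needs at least 2 samples")
  }
  if (cfg$biological_cv < 0 || cfg$technical_cv < 0) {
    stop("coefficients of variation must be >= 0")
  }
  if (cfg$drift_amplitude < 0 || cfg$drift_amplitude >= 1) {
    stop("drift_amplitude must be in [0, 1)")
  }
  if (cfg$n_glycoproteins > cfg$n_proteins) {
    stop("n_glycoproteins cannot exceed n_proteins")
  }
  if (cfg$n_glycopeptides < cfg$n_glycoproteins) {
    stop("need at least one glycopeptide per glycoprotein: ",
         cfg$n_glycopeptides, " < ", cfg$n_glycoproteins)
  }
  class(cfg) <- "sim_config"
  cfg
}

# serum glycoprotein symbols seen on MRM panels; padded with synthetic
# symbols when the configured panel is wider
.protein_symbols <- function(n) {
  known <- c("A2MG", "HPT", "AGP1", "A1AT", "CFAH", "TRFE", "VTNC", "CERU",
             "AFAM", "IGG1", "HEMO", "APOC3", "CLU", "APOM", "A1BG", "APOA1",
             "APOD", "IGA1", "IGM", "KNG1", "PON1", "VIME", "CO4A", "ORM2",
             "C8A", "FIBA", "FIBB", "FIBG", "ANT3", "APOB", "APOE", "ATRN",
             "B2GP1", "C1S", "C3", "C5", "C6", "C9", "CBG", "CFAB", "CFAI",
             "CHLE", "F13B", "FETUA", "GELS", "HRG", "IC1", "ITIH4", "LUM",
             "PLMN", "PROS", "RET4", "SHBG", "THRB", "TTHY", "ZA2G", "AACT")
  if (n <= length(known)) known[seq_len(n)]
  else c(known, sprintf("GP%02d", seq_len(n - length(known))))
}

# glycan code vocabulary observed on serum MRM panels
.glycan_vocab <- c("5200", "5400", "5401", "5402", "5410", "5411", "5412",
                   "5431", "5511", "6200", "6300",
                   "6500", "6501", "6502", "6503", "6511", "6512", "6513",
                   "7600", "7601", "7602", "7604", "7613", "7614")

#' Build a synthetic marker panel (manifest)
#'
#' Generates a marker manifest with the configured dimensions: glycopeptide
#' markers spread over the glycoprotein subset (every glycoprotein gets at
#' least one), glycan codes drawn from the composition vocabulary typical of
#' abundant serum glycoproteins, and one non-glycosylated peptide marker per
#' monitored protein.
#'
#' @param config a [sim_config()].
#' @return data frame with columns \code{marker_id}, \code{protein},
#'   \code{sites} (semicolon-separated residue positions), \code{glycan_code}
#'   (empty string for peptides) and \code{is_peptide}.
#' @export
make_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  proteins <- .protein_symbols(config$n_proteins)
  glyco_prot <- proteins[seq_len(config$n_glycoproteins)]

  # spread glycopeptides over glycoproteins, >=1 each
  extra <- config$n_glycopeptides - config$n_glycoproteins
  alloc <- rep(1L, config$n_glycoproteins)
  if (extra > 0L) {
    add <- tabulate(sample.int(config$n_glycoproteins, extra, replace = TRUE),
                    nbins = config$n_glycoproteins)
    alloc <- alloc + add
  }

  rows <- vector("list", config$n_glycoproteins)
  for (i in seq_along(glyco_prot)) {
    k <- alloc[i]
    # a protein carries a few glycosites; each site a few glycoforms
    n_sites <- max(1L, ceiling(k / 4L))
    sites <- sort(sample(20:1450, n_sites))
    site_of <- sites[1L + (seq_len(k) - 1L) %% n_sites]
    codes <- character(k)
    for (s in unique(site_of)) {
      idx <- which(site_of == s)
      codes[idx] <- sample(.glycan_vocab, length(idx),
                           replace = length(idx) > length(.glycan_vocab))
    }
    # duplicated (site, code) pairs within a protein collapse to one row;
    # resample until unique (vocabulary is ample at these densities)
    while (anyDuplicated(paste(site_of, codes))) {
      d <- which(duplicated(paste(site_of, codes)))
      codes[d] <- sample(.glycan_vocab, length(d), replace = TRUE)
    }
    rows[[i]] <- data.frame(protein = glyco_prot[i], site = site_of,
                            glycan_code = codes, stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, rows)
  g$marker_id <- paste0(g$protein, " (", g$site, ") – ", g$glycan_code)
  glyco <- data.frame(marker_id = g$marker_id, protein = g$protein,
                      sites = as.character(g$site),
                      glycan_code = g$glycan_code, is_peptide = FALSE,
                      stringsAsFactors = FALSE)

  pep_seq <- vapply(seq_along(proteins), function(i) {
    paste(sample(c("A", "D", "E", "F", "G", "H", "I", "K", "L", "N", "P",
                   "Q", "R", "S", "T", "V", "W", "Y"), 10, replace = TRUE),
          collapse = "")
  }, character(1))
  pep <- data.frame(
    marker_id = paste0(proteins, " – ", pep_seq),
    protein = proteins, sites = "", glycan_code = "",
    is_peptide = TRUE, stringsAsFactors = FALSE
  )
  manifest <- rbind(glyco, pep)
  rownames(manifest) <- NULL
  manifest
}

# ground-truth log2 effects per marker implied by config + motif class
.true_effects <- function(manifest, config) {
  l2n <- numeric(nrow(manifest))
  l2h <- numeric(nrow(manifest))
  is_g <- !manifest$is_peptide
  if (any(is_g)) {
    mot <- classify_motif(manifest$glycan_code[is_g])
    up <- mot$fucosylated & mot$sialylation_count >= 1L
    dn <- !mot$fucosylated & mot$sialylation_count >= 2L
    l2n[is_g][up] <- config$effect_nash_up
    l2h[is_g][up] <- config$effect_hcc_up
    l2n[is_g][dn] <- config$effect_nash_down
    l2h[is_g][dn] <- config$effect_hcc_down
  }
  if (!is.null(config$effect_table)) {
    et <- config$effect_table
    stopifnot(all(c("marker_id", "contrast", "log2fc") %in% names(et)))
    for (r in seq_len(nrow(et))) {
      i <- match(et$marker_id[r], manifest$marker_id)
      if (is.na(i)) stop("effect_table marker not in panel: ", et$marker_id[r])
      if (et$contrast[r] == "NASH") l2n[i] <- et$log2fc[r]
      else if (et$contrast[r] == "HCC") l2h[i] <- et$log2fc[r]
      else stop("effect_table contrast must be 'NASH' or 'HCC'")
    }
  }
  data.frame(marker_id = manifest$marker_id,
             log2fc_nash = l2n, log2fc_hcc = l2h,
             stringsAsFactors = FALSE)
}

# interleave study samples with reference pools at every qc_interval-th
# position of the run (positions qc, 2*qc, ... are pools)
.build_layout <- function(study_ids, qc_interval) {
  n <- length(study_ids)
  pos <- 0L
  placed <- 0L
  ids <- character(0)
  is_ref <- logical(0)
  while (placed < n) {
    pos <- pos + 1L
    if (pos %% qc_interval == 0L) {
      ids <- c(ids, NA_character_)
      is_ref <- c(is_ref, TRUE)
    } else {
      placed <- placed + 1L
      ids <- c(ids, study_ids[placed])
      is_ref <- c(is_ref, FALSE)
    }
  }
  # close the run on a pool so the last study injections are bracketed
  if (!is_ref[length(is_ref)]) {
    ids <- c(ids, NA_character_)
    is_ref <- c(is_ref, TRUE)
    pos <- pos + 1L
  }
  ids[is_ref] <- sprintf("REF_%02d", seq_len(sum(is_ref)))
  data.frame(injection_index = seq_len(pos), sample_id = ids,
             is_reference = is_ref, stringsAsFactors = FALSE)
}

#' Simulate a synthetic MRM cohort
#'
#' Generates the full study: a sample sheet with phenotype, age and sex; a
#' run layout with randomized study-sample order and reference-pool
#' injections at every \code{qc_interval}-th position; a raw abundance
#' matrix (markers x injections) built as
#' baseline x phenotype effect x age/sex effect x drift x lognormal noise;
#' and the ground truth (true log2 fold changes, drift-free expectations)
#' needed for recovery tests. Reference pools share one fixed composition
#' and are subject only to drift and technical noise.
#'
#' @param config a [sim_config()].
#' @param manifest optional pre-built panel; defaults to
#'   \code{make_panel(config)}.
#' @return list of class \code{"glyco_sim"} with elements \code{manifest},
#'   \code{sheet}, \code{layout}, \code{raw} (matrix), \code{truth} (list
#'   with \code{effects} and \code{expected} drift-free study matrix) and
#'   \code{config}.
#' @export
simulate_cohort <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(manifest)) manifest <- make_panel(config)
  set.seed(config$seed + 1L)

  n_study <- config$n_control + config$n_nash + config$n_hcc
  phen <- c(rep("control", config$n_control), rep("NASH", config$n_nash),
            rep("HCC", config$n_hcc))
  ids <- sprintf("S%03d", seq_len(n_study))
  age_rng <- list(control = c(23, 91), NASH = c(45, 70), HCC = c(32, 85))
  male_p <- c(control = 26 / 56, NASH = 10 / 23, HCC = 15 / 19)
  age <- vapply(phen, function(p)
    round(stats::runif(1, age_rng[[p]][1], age_rng[[p]][2])), numeric(1))
  sex <- vapply(phen, function(p)
    if (stats::runif(1) < male_p[[p]]) "M" else "F", character(1))

  order_ids <- sample(ids)  # randomized injection order
  layout <- .build_layout(order_ids, config$qc_interval)
  sheet <- data.frame(
    sample_id = ids, phenotype = phen, age = as.numeric(age), sex = sex,
    injection_index = layout$injection_index[match(ids, layout$sample_id)],
    is_reference = FALSE, stringsAsFactors = FALSE
  )
  ref <- layout[layout$is_reference, , drop = FALSE]
  sheet <- rbind(sheet, data.frame(
    sample_id = ref$sample_id, phenotype = "reference_pool",
    age = NA_real_, sex = NA_character_,
    injection_index = ref$injection_index, is_reference = TRUE,
    stringsAsFactors = FALSE
  ))
  sheet <- sheet[order(sheet$injection_index), ]
  rownames(sheet) <- NULL

  m <- nrow(manifest)
  n_inj <- nrow(layout)
  baseline <- 10^stats::runif(m, 4, 7)
  effects <- .true_effects(manifest, config)

  # drift trend: exponential decay to (1 - amplitude) at the final injection
  last <- max(layout$injection_index)
  frac <- if (last > 1L) (layout$injection_index - 1L) / (last - 1L) else 0
  trend <- (1 - config$drift_amplitude)^frac
  drift <- matrix(rep(trend, each = m), nrow = m)
  if (config$drift_jitter > 0) {
    jit <- stats::rnorm(m, 0, config$drift_jitter)
    drift <- drift^exp(jit)  # per-marker speed-up/slow-down of the decay
  }

  sd_bio <- sqrt(log(1 + config$biological_cv^2))
  sd_tec <- sqrt(log(1 + config$technical_cv^2))

  # drift-free expected study abundances (biology + covariates, no noise)
  idx <- match(layout$sample_id, sheet$sample_id)
  phen_i <- sheet$phenotype[idx]
  age_i <- sheet$age[idx]
  sex_i <- sheet$sex[idx]
  l2 <- matrix(0, nrow = m, ncol = n_inj)
  l2[, phen_i == "NASH"] <- effects$log2fc_nash
  l2[, phen_i == "HCC"] <- effects$log2fc_hcc
  cov_l2 <- ifelse(is.na(age_i), 0,
                   config$age_effect_log2 * (age_i - 60) +
                     config$sex_effect_log2 * (sex_i == "M"))
  expected <- baseline * 2^(l2 + matrix(rep(cov_l2, each = m), nrow = m))

  noise <- matrix(1, nrow = m, ncol = n_inj)
  is_ref <- layout$is_reference
  if (sd_bio > 0 && any(!is_ref)) {
    noise[, !is_ref] <- noise[, !is_ref] *
      exp(matrix(stats::rnorm(m * sum(!is_ref), -sd_bio^2 / 2, sd_bio),
                 nrow = m))
  }
  if (sd_tec > 0) {
    noise <- noise * exp(matrix(stats::rnorm(m * n_inj, -sd_tec^2 / 2, sd_tec),
                                nrow = m))
  }
  raw <- expected * drift * noise
  if (config$missing_rate > 0) {
    study_cells <- which(rep(!is_ref, each = m))
    nas <- sample(study_cells,
                  floor(config$missing_rate * length(study_cells)))
    raw[nas] <- NA_real_
  }
  dimnames(raw) <- list(manifest$marker_id, layout$sample_id)
  expected_study <- expected[, !is_ref, drop = FALSE]
  dimnames(expected_study) <- list(manifest$marker_id,
                                   layout$sample_id[!is_ref])

  out <- list(manifest = manifest, sheet = sheet, layout = layout, raw = raw,
              truth = list(effects = effects, baseline = baseline,
                           expected = expected_study),
              config = config)
  class(out) <- "glyco_sim"
  out
}

#' @export
print.glyco_sim <- function(x, ...) {
  n_g <- sum(!x$manifest$is_peptide)
  cat("Synthetic MRM glycoproteomics cohort (seed ", x$config$seed, ")\n",
      sep = "")
  cat("  panel   : ", n_g, " glycopeptides / ",
      length(unique(x$manifest$protein[!x$manifest$is_peptide])),
      " glycoproteins + ", sum(x$manifest$is_peptide), " peptides\n", sep = "")
  ph <- table(x$sheet$phenotype[!x$sheet$is_reference])
  cat("  cohort  : ", paste(names(ph), ph, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  run     : ", nrow(x$layout), " injections, ",
      sum(x$layout$is_reference), " reference pools (every ",
      x$config$qc_interval, "th)\n", sep = "")
  invisible(x)
}
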