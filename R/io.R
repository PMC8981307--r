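#' Read a wide abundance table
#'
#' CSV with \code{marker_id} as first column and one numeric column per
#' injection. Lines starting with \code{#} (e.g. the seed header written by
#' the simulation writers) are skipped. Duplicate marker ids and non-numeric
#' cells are errors; missing values are rejected because the downstream
#' model assumes complete, strictly positive areas.
#'
#' @param path CSV file path.
#' @return numeric matrix markers x injections.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        colClasses = "character")
  if (ncol(df) < 2L) stop("abundance table needs marker_id plus >= 1 sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate marker_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ids <- .normalize_dashes(ids)
  body <- as.matrix(df[-1L])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or missing value at marker ", sQuote(ids[bad[1L, 1L]]),
         ", column ", sQuote(colnames(df)[-1L][bad[1L, 2L]]))
  }
  dimnames(num) <- list(ids, colnames(df)[-1L])
  num
}

#' Write a wide abundance table
#'
#' @param x abundance matrix (markers x samples) or \code{norm_abundance}.
#' @param path output CSV path.
#' @param seed optional seed recorded as a \code{# seed:} header comment.
#' @export
write_abundance_table <- function(x, path, seed = NULL) {
  x <- .abundance_values(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  df <- data.frame(marker_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.normalize_dashes <- function(x) gsub("\\s*[-–—]\\s*", " – ", x)

.phenotype_vocab <- c("control", "NASH", "HCC", "benign", "reference_pool")

#' Read a sample sheet and reconstruct the run layout
#'
#' Expects columns \code{sample_id}, \code{phenotype}, \code{age},
#' \code{sex}, \code{injection_index}, \code{is_reference}. Phenotypes must
#' come from the study vocabulary (control, NASH, HCC, benign,
#' reference_pool); injection indices must be unique.
#'
#' @param path CSV file path.
#' @return list with \code{sheet} (study + reference rows) and \code{layout}
#'   (injection order with reference flags).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype", "age", "sex", "injection_index",
            "is_reference")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$injection_index)) {
    stop("duplicate injection_index: ",
         paste(unique(df$injection_index[duplicated(df$injection_index)]),
               collapse = ", "))
  }
  df$is_reference <- as.logical(df$is_reference)
  bad <- setdiff(unique(df$phenotype), .phenotype_vocab)
  if (length(bad)) {
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.phenotype_vocab, collapse = ", "), ")")
  }
  df <- df[order(df$injection_index), ]
  rownames(df) <- NULL
  layout <- data.frame(injection_index = df$injection_index,
                       sample_id = df$sample_id,
                       is_reference = df$is_reference,
                       stringsAsFactors = FALSE)
  list(sheet = df, layout = layout)
}

#' Write a sample sheet
#'
#' @param sheet sample sheet data frame.
#' @param path output CSV path.
#' @param seed optional seed header comment.
#' @export
write_sample_sheet <- function(sheet, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(sheet, con, row.names = FALSE)
  invisible(path)
}

#' Read a marker manifest
#'
#' Columns: \code{marker_id}, \code{protein}, \code{sites}
#' (semicolon-separated residue positions), \code{glycan_code} (empty for
#' peptide markers), \code{is_peptide}. Dashes in marker ids are normalized
#' to the canonical en dash; glycan codes are validated.
#'
#' @param path CSV file path.
#' @return manifest data frame.
#' @export
read_marker_manifest <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("marker_id", "protein", "sites", "glycan_code", "is_peptide")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  }
  df$marker_id <- .normalize_dashes(df$marker_id)
  df$is_peptide <- as.logical(df$is_peptide)
  if (anyDuplicated(df$marker_id)) {
    stop("duplicate marker_id in manifest: ",
         paste(unique(df$marker_id[duplicated(df$marker_id)]), collapse = ", "))
  }
  has_code <- nzchar(df$glycan_code)
  if (any(df$is_peptide == has_code)) {
    stop("each marker must be either a peptide or carry a glycan code: ",
         paste(utils::head(df$marker_id[df$is_peptide == has_code], 5),
               collapse = ", "))
  }
  if (any(has_code)) parse_glycan_code(df$glycan_code[has_code])
  df
}

#' Write a marker manifest
#'
#' @param manifest manifest data frame.
#' @param path output CSV path.
#' @param seed optional seed header comment.
#' @export
write_marker_manifest <- function(manifest, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(manifest, con, row.names = FALSE)
  invisible(path)
}

# stable short hash of a config (djb2 over the serialized JSON)
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Assemble and validate a pipeline configuration
#'
#' @param seed integer seed used by every stochastic stage.
#' @param out_dir output directory for stage artifacts.
#' @param abundance,sample_sheet,manifest input CSV paths; all three NULL
#'   means a synthetic cohort is simulated from \code{sim}.
#' @param sim a [sim_config()] used when simulating (its seed is overridden
#'   by \code{seed}).
#' @param qc_interval reference-pool spacing expected in the layout.
#' @param p_alpha,fdr_alpha significance levels of the cascade.
#' @param scope relative-abundance scope.
#' @param classify_contrast character(2): phenotypes for the LOOCV
#'   classifier (default NASH vs HCC).
#' @param penalty classifier penalty.
#' @param ... rejected: unknown keys are configuration errors.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed, out_dir = tempfile("glycomrm_"),
                            abundance = NULL, sample_sheet = NULL,
                            manifest = NULL, sim = NULL,
                            qc_interval = 10L, p_alpha = 0.05,
                            fdr_alpha = 0.05, scope = "global",
                            classify_contrast = c("NASH", "HCC"),
                            penalty = "lasso", ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  if (missing(seed)) stop("pipeline seed is required")
  paths <- list(abundance = abundance, sample_sheet = sample_sheet,
                manifest = manifest)
  given <- !vapply(paths, is.null, logical(1))
  if (any(given) && !all(given)) {
    stop("provide all of abundance/sample_sheet/manifest, or none (simulate)")
  }
  if (!any(given) && is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              abundance = abundance, sample_sheet = sample_sheet,
              manifest = manifest, sim = sim,
              qc_interval = as.integer(qc_interval),
              p_alpha = p_alpha, fdr_alpha = fdr_alpha, scope = scope,
              classify_contrast = classify_contrast, penalty = penalty)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate (when no input files are given) -> drift correction ->
#' differential testing over the three contrasts -> significance cascade +
#' progression screen -> motif summary -> LOOCV classification, writing
#' every stage artifact plus a run manifest (config hash, seed) to the
#' output directory. Identical config + seed reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of class \code{"glyco_run"} with all stage
#'   results and \code{paths} of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list()

  if (is.null(config$abundance)) {
    sim <- stage("simulate", {
      sc <- config$sim
      sc$seed <- config$seed
      simulate_cohort(sc)
    })
    manifest <- sim$manifest; sheet <- sim$sheet; layout <- sim$layout
    raw <- sim$raw
    paths$abundance <- file.path(config$out_dir, "raw_abundance.csv")
    paths$sample_sheet <- file.path(config$out_dir, "sample_sheet.csv")
    paths$manifest <- file.path(config$out_dir, "manifest.csv")
    write_abundance_table(raw, paths$abundance, seed = config$seed)
    write_sample_sheet(sheet, paths$sample_sheet, seed = config$seed)
    write_marker_manifest(manifest, paths$manifest, seed = config$seed)
  } else {
    sim <- NULL
    raw <- stage("read abundance", read_abundance_table(config$abundance))
    ss <- stage("read sample sheet", read_sample_sheet(config$sample_sheet))
    sheet <- ss$sheet; layout <- ss$layout
    manifest <- stage("read manifest", read_marker_manifest(config$manifest))
    miss <- setdiff(layout$sample_id, colnames(raw))
    if (length(miss)) {
      stop("stage 'read abundance' failed: abundance table lacks sample(s) ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }

  norm <- stage("normalize", drift_correct(raw, layout))
  paths$normalized <- file.path(config$out_dir, "normalized_abundance.csv")
  write_abundance_table(norm, paths$normalized, seed = config$seed)
  paths$qc <- file.path(config$out_dir, "qc_report.json")
  jsonlite::write_json(norm$qc, paths$qc, dataframe = "rows", digits = NA,
                       na = "null")

  contrasts <- list(control_vs_NASH = c("control", "NASH"),
                    control_vs_HCC = c("control", "HCC"),
                    NASH_vs_HCC = c("NASH", "HCC"))
  diffs <- stage("differential", lapply(contrasts, function(ct)
    adjusted_fold_change(norm, sheet, ct)))
  for (nm in names(diffs)) {
    p <- file.path(config$out_dir, paste0("differential_", nm, ".csv"))
    utils::write.csv(as.data.frame(diffs[[nm]]), p, row.names = FALSE)
    paths[[paste0("differential_", nm)]] <- p
  }

  screen <- stage("progression screen",
                  progression_screen(norm, sheet, fdr_alpha = config$fdr_alpha))
  cascade <- stage("cascade", significance_cascade(
    diffs, manifest, p_alpha = config$p_alpha, fdr_alpha = config$fdr_alpha,
    unidirectional = screen$marker_id[screen$passes]))
  paths$cascade <- file.path(config$out_dir, "cascade_report.json")
  jsonlite::write_json(unclass(cascade), paths$cascade, auto_unbox = TRUE,
                       digits = NA)

  motifs <- stage("motifs", {
    rel <- relative_abundance(raw, manifest, scope = config$scope)
    rel_study <- rel[, layout$sample_id[!layout$is_reference], drop = FALSE]
    motif_abundance_summary(rel_study, group_by_motif(manifest), sheet)
  })
  paths$motifs <- file.path(config$out_dir, "motif_summary.csv")
  utils::write.csv(as.data.frame(motifs), paths$motifs, row.names = FALSE)

  cvrep <- stage("classify", {
    ct <- config$classify_contrast
    ids <- sheet$sample_id[sheet$phenotype %in% ct]
    feats <- t(.abundance_values(norm)[, ids, drop = FALSE])
    labs <- factor(sheet$phenotype[match(ids, sheet$sample_id)], levels = ct)
    loocv_evaluate(log2(feats), labs, penalty = config$penalty,
                   seed = config$seed)
  })
  paths$cv <- file.path(config$out_dir, "cv_report.json")
  jsonlite::write_json(list(
    auc_train = cvrep$auc_train, auc_test = cvrep$auc_test,
    coverage = cvrep$coverage,
    prob = data.frame(sample_id = names(cvrep$prob) %||%
                        seq_along(cvrep$prob),
                      label = as.character(cvrep$labels),
                      prob = cvrep$prob)),
    paths$cv, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  paths$roc <- file.path(config$out_dir, "roc_test.csv")
  utils::write.csv(cvrep$roc_test$curve, paths$roc, row.names = FALSE)

  run_manifest <- list(
    seed = config$seed,
    config_hash = .config_hash(config[setdiff(names(config), "out_dir")]),
    r_version = as.character(getRversion()),
    finished = TRUE
  )
  paths$run_manifest <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(run_manifest, paths$run_manifest, auto_unbox = TRUE)

  message(sprintf("pipeline finished in %.1fs (seed %d)",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config$seed))
  out <- list(sim = sim, norm = norm, differential = diffs, screen = screen,
              cascade = cascade, motifs = motifs, cv = cvrep,
              config = config, paths = paths)
  class(out) <- "glyco_run"
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.glyco_run <- function(x, ...) {
  cat("glycoMRM pipeline run (seed ", x$config$seed, ")\n", sep = "")
  print(x$cascade)
  cat(sprintf("  LOOCV %s vs %s: test AUROC %.3f\n",
              x$config$classify_contrast[1L], x$config$classify_contrast[2L],
              x$cv$auc_test))
  cat("  artifacts in ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}
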