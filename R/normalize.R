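#' Drift-correct raw peak areas against reference-pool injections
#'
#' Instrument response in a long MRM run decays (or wanders) over the
#' injection sequence. Because a reference pooled serum digest is injected at
#' a fixed interval, its repeated measurements trace the drift for every
#' marker. The correction estimates, per marker, a reference trend at each
#' study injection by linear interpolation between the bracketing pool
#' measurements (flat extrapolation before the first and after the last
#' pool) and rescales:
#' \deqn{norm_{m,i} = raw_{m,i} / trend_m(i) \times median_m(pools)}
#' which keeps normalized values on the raw-area scale. An alternative
#' \code{method = "pool_median"} divides by a single run-wide pool median per
#' marker (no local trend), which removes only level, not drift.
#'
#' @param raw matrix of raw abundances, markers x injections; column names
#'   must match \code{layout$sample_id}.
#' @param layout run layout data frame (\code{injection_index},
#'   \code{sample_id}, \code{is_reference}) as produced by
#'   [simulate_cohort()] or [read_sample_sheet()].
#' @param method \code{"interpolate"} (default, local trend) or
#'   \code{"pool_median"}.
#' @return object of class \code{"norm_abundance"}: list with \code{values}
#'   (markers x study samples, pools excluded), \code{qc} (per-marker pool CV
#'   before/after leave-one-pool-out correction), \code{method},
#'   \code{skipped} (markers with nonpositive pool measurements, left
#'   uncorrected and flagged).
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 1, n_control = 9, n_nash = 5,
#'                                   n_hcc = 5, n_proteins = 4,
#'                                   n_glycoproteins = 3,
#'                                   n_glycopeptides = 12, qc_interval = 5))
#' norm <- drift_correct(sim$raw, sim$layout)
#' @export
drift_correct <- function(raw, layout, method = c("interpolate", "pool_median")) {
  method <- match.arg(method)
  raw <- .as_abundance_matrix(raw)
  .check_layout(layout)
  if (!setequal(colnames(raw), layout$sample_id)) {
    stop("column names of raw matrix do not match layout sample ids")
  }
  raw <- raw[, layout$sample_id, drop = FALSE]
  ref_idx <- which(layout$is_reference)
  if (length(ref_idx) < 2L) {
    stop("need at least 2 reference-pool injections for drift correction, got ",
         length(ref_idx))
  }
  ref_pos <- layout$injection_index[ref_idx]
  study <- which(!layout$is_reference)
  study_pos <- layout$injection_index[study]

  m <- nrow(raw)
  refs <- raw[, ref_idx, drop = FALSE]
  skipped <- rownames(raw)[apply(refs, 1L, function(v) any(!is.finite(v) | v <= 0))]
  if (length(skipped)) {
    warning(length(skipped), " marker(s) with nonpositive/missing reference ",
            "measurements left uncorrected: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  }

  values <- raw[, study, drop = FALSE]
  for (r in seq_len(m)) {
    if (rownames(raw)[r] %in% skipped) next
    pool <- refs[r, ]
    if (method == "interpolate") {
      trend <- stats::approx(ref_pos, pool, xout = study_pos, rule = 2)$y
    } else {
      trend <- rep(stats::median(pool), length(study_pos))
    }
    values[r, ] <- raw[r, study] / trend * stats::median(pool)
  }

  qc <- .pool_qc(raw, ref_pos, ref_idx, skipped, method)
  out <- list(values = values, qc = qc, method = method,
              skipped = skipped, layout = layout)
  class(out) <- "norm_abundance"
  out
}

# leave-one-pool-out QC: each pool injection corrected by the trend fitted on
# the remaining pools; CV across pools before vs after
.pool_qc <- function(raw, ref_pos, ref_idx, skipped, method) {
  cv <- function(v) stats::sd(v) / mean(v)
  m <- nrow(raw)
  before <- after <- rep(NA_real_, m)
  for (r in seq_len(m)) {
    if (rownames(raw)[r] %in% skipped) next
    pool <- raw[r, ref_idx]
    before[r] <- cv(pool)
    corr <- vapply(seq_along(pool), function(j) {
      if (method == "interpolate" && length(pool) > 2L) {
        tr <- stats::approx(ref_pos[-j], pool[-j], xout = ref_pos[j],
                            rule = 2)$y
      } else {
        tr <- stats::median(pool[-j])
      }
      pool[j] / tr * stats::median(pool[-j])
    }, numeric(1))
    after[r] <- cv(corr)
  }
  data.frame(marker_id = rownames(raw), cv_before = before, cv_after = after,
             stringsAsFactors = FALSE)
}

#' @export
print.norm_abundance <- function(x, ...) {
  cat("Drift-corrected abundance matrix (", x$method, ")\n", sep = "")
  cat("  ", nrow(x$values), " markers x ", ncol(x$values),
      " study samples; ", sum(x$layout$is_reference),
      " reference pools used\n", sep = "")
  ok <- stats::complete.cases(x$qc[c("cv_before", "cv_after")])
  if (any(ok)) {
    cat(sprintf("  median pool CV: %.3f before -> %.3f after (LOO)\n",
                stats::median(x$qc$cv_before[ok]),
                stats::median(x$qc$cv_after[ok])))
  }
  if (length(x$skipped)) {
    cat("  skipped markers:", length(x$skipped), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.norm_abundance <- function(x, ...) x$values

# accept either a norm_abundance or a plain matrix everywhere downstream
.abundance_values <- function(x) {
  if (inherits(x, "norm_abundance")) x$values else .as_abundance_matrix(x)
}

.as_abundance_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("abundance matrix needs marker row names and sample column names")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicated marker ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  storage.mode(x) <- "double"
  x
}

.check_layout <- function(layout) {
  need <- c("injection_index", "sample_id", "is_reference")
  if (!all(need %in% names(layout))) {
    stop("layout must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(layout$injection_index)) {
    stop("duplicate injection_index in layout: ",
         paste(unique(layout$injection_index[duplicated(layout$injection_index)]),
               collapse = ", "))
  }
  invisible(layout)
}

#' Relative abundance of glycopeptides
#'
#' Expresses each glycopeptide as the ratio of its raw abundance to the
#' summed raw abundances of all glycopeptides in scope for that sample.
#' Non-glycosylated peptide markers are excluded from both numerator and
#' denominator. Scope \code{"global"} uses all glycopeptides (values sum to
#' 1 per sample); \code{"per_protein"} and \code{"per_site"} restrict the
#' denominator to glycoforms of the same protein, or of the same
#' glycosylation site, so that glycoform distributions can be compared
#' within a carrier.
#'
#' @param raw abundance matrix (markers x samples) or a
#'   \code{norm_abundance}.
#' @param manifest marker manifest data frame (needs \code{marker_id},
#'   \code{protein}, \code{sites}, \code{is_peptide}).
#' @param scope one of \code{"global"}, \code{"per_protein"},
#'   \code{"per_site"}.
#' @return matrix of relative abundances (glycopeptide markers x samples)
#'   with attributes \code{scope} and \code{groups} (the scope grouping).
#' @examples
#' m <- matrix(c(2, 3, 5), 3, 1,
#'             dimnames = list(c("P (1) – 5402", "P (2) – 5401",
#'                               "Q (9) – 6503"), "s1"))
#' mf <- data.frame(marker_id = rownames(m), protein = c("P", "P", "Q"),
#'                  sites = c("1", "2", "9"), glycan_code = c("5402", "5401",
#'                  "6503"), is_peptide = FALSE)
#' relative_abundance(m, mf)  # 0.2, 0.3, 0.5
#' @export
relative_abundance <- function(raw, manifest,
                               scope = c("global", "per_protein", "per_site")) {
  scope <- match.arg(scope)
  x <- .abundance_values(raw)
  glyco <- manifest[!manifest$is_peptide, , drop = FALSE]
  missing_m <- setdiff(glyco$marker_id, rownames(x))
  if (length(missing_m)) {
    stop("glycopeptide markers absent from abundance matrix: ",
         paste(utils::head(missing_m, 5), collapse = ", "))
  }
  x <- x[glyco$marker_id, , drop = FALSE]
  groups <- switch(scope,
    global = rep("all", nrow(glyco)),
    per_protein = glyco$protein,
    per_site = paste0(glyco$protein, ":", glyco$sites)
  )
  out <- x
  for (g in unique(groups)) {
    rows <- groups == g
    denom <- colSums(x[rows, , drop = FALSE])
    zero <- !is.finite(denom) | denom == 0
    if (any(zero)) {
      stop("zero denominator in scope group ", sQuote(g), " for sample(s) ",
           paste(colnames(x)[zero], collapse = ", "))
    }
    out[rows, ] <- sweep(x[rows, , drop = FALSE], 2L, denom, "/")
  }
  attr(out, "scope") <- scope
  attr(out, "groups") <- stats::setNames(groups, glyco$marker_id)
  out
}
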