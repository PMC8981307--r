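#' Covariate-adjusted differential abundance for one contrast
#'
#' Per marker, fits least squares of log2(normalized abundance) on a group
#' indicator plus the covariates (age in years, sex as a binary indicator)
#' over the samples of the two contrast groups. The adjusted fold change is
#' \code{2^beta} for the group coefficient, oriented as first-named group
#' over second; the p-value is the two-sided Wald t test of that
#' coefficient. Benjamini-Hochberg q-values are attached across markers.
#'
#' The fit is vectorized: one QR decomposition of the shared design matrix
#' serves every marker.
#'
#' @param norm \code{norm_abundance} or matrix (markers x study samples).
#' @param sheet sample sheet data frame (\code{sample_id}, \code{phenotype},
#'   \code{age}, \code{sex}); reference-pool rows are ignored.
#' @param contrast character(2): the two phenotype labels, first over second
#'   (e.g. \code{c("control", "HCC")} reports control/HCC).
#' @param covariates subset of \code{c("age", "sex")} to adjust for.
#' @param adjust if \code{FALSE}, drop all covariates and report the raw
#'   ratio of geometric means.
#' @return data frame of class \code{"glyco_diff"}: \code{marker_id},
#'   \code{fold_change}, \code{log2fc}, \code{se}, \code{p_value},
#'   \code{q_value}, with attributes \code{contrast} and \code{n}.
#' @export
adjusted_fold_change <- function(norm, sheet, contrast,
                                 covariates = c("age", "sex"),
                                 adjust = TRUE) {
  x <- .abundance_values(norm)
  stopifnot(length(contrast) == 2L, all(nzchar(contrast)))
  if (!adjust) covariates <- character(0)
  covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  if (!is.null(sheet$is_reference)) {
    sheet <- sheet[!sheet$is_reference, , drop = FALSE]
  }
  sheet <- sheet[sheet$phenotype %in% contrast, , drop = FALSE]
  keep <- intersect(colnames(x), sheet$sample_id)
  sheet <- sheet[match(keep, sheet$sample_id), , drop = FALSE]
  x <- x[, keep, drop = FALSE]
  n_per <- table(factor(sheet$phenotype, levels = contrast))
  if (any(n_per < 3L)) {
    stop("each contrast group needs >= 3 samples; got ",
         paste(names(n_per), n_per, sep = "=", collapse = ", "))
  }
  if (any(!is.finite(x) | x <= 0)) {
    stop("abundances must be strictly positive and finite for log2 modelling")
  }

  design <- cbind(`(Intercept)` = 1,
                  group = as.numeric(sheet$phenotype == contrast[1L]))
  if ("age" %in% covariates && length(covariates)) {
    design <- cbind(design, age = as.numeric(sheet$age))
  }
  if ("sex" %in% covariates) {
    design <- cbind(design, sexM = as.numeric(sheet$sex == "M"))
  }
  # drop collinear covariates (e.g. sex constant within the contrast)
  qr0 <- qr(design)
  if (qr0$rank < ncol(design)) {
    keep_cols <- qr0$pivot[seq_len(qr0$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep_cols)]
    if ("group" %in% dropped) stop("group indicator is collinear with covariates")
    warning("dropping collinear covariate(s): ", paste(dropped, collapse = ", "))
    design <- design[, sort(keep_cols), drop = FALSE]
    qr0 <- qr(design)
  }

  y <- t(log2(x))                      # samples x markers
  coefs <- qr.coef(qr0, y)             # p x markers
  fitted <- design %*% coefs
  resid <- y - fitted
  df <- nrow(design) - ncol(design)
  s2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr0))
  g <- match("group", colnames(design))
  se <- sqrt(s2 * xtx_inv[g, g])
  beta <- coefs[g, ]
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)

  out <- data.frame(
    marker_id = rownames(x),
    fold_change = 2^beta,
    log2fc = beta,
    se = se,
    p_value = p,
    q_value = bh_fdr(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "contrast") <- contrast
  attr(out, "n") <- as.integer(n_per)
  attr(out, "covariates") <- covariates
  class(out) <- c("glyco_diff", "data.frame")
  out
}

#' @export
print.glyco_diff <- function(x, ...) {
  ct <- attr(x, "contrast")
  n <- attr(x, "n")
  cat("Differential abundance: ", ct[1L], "/", ct[2L],
      "  (n = ", n[1L], "/", n[2L], ")\n", sep = "")
  cat("  ", nrow(x), " markers; ", sum(x$p_value < 0.05), " with p < 0.05; ",
      sum(x$q_value <= 0.05), " with q <= 0.05\n", sep = "")
  invisible(x)
}

#' @export
summary.glyco_diff <- function(object, alpha = 0.05, ...) {
  o <- object[order(object$p_value), ]
  cat("Top markers by p-value:\n")
  print(utils::head(as.data.frame(o), 10), digits = 3)
  invisible(o)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Classic step-up FDR control: with ordered p-values \eqn{p_{(1)} \le \dots
#' \le p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, capped at 1,
#' reported in the original input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Significance-intersection cascade across contrasts
#'
#' Reproduces the set logic used to narrow a marker panel: per-contrast
#' significant sets at \code{p < p_alpha} and at BH FDR \code{<= fdr_alpha},
#' the intersection of the two control contrasts at FDR level, an optional
#' unidirectional (progression) subset split into glycopeptides and
#' peptides, and the distinct-protein roll-up.
#'
#' @param results named list of \code{glyco_diff} results; names must
#'   include \code{"control_vs_NASH"} and \code{"control_vs_HCC"}
#'   (\code{"NASH_vs_HCC"} is reported when present).
#' @param manifest marker manifest (to split glycopeptides from peptides and
#'   roll up proteins).
#' @param p_alpha,fdr_alpha significance levels (defaults 0.05).
#' @param unidirectional optional character vector of marker ids that passed
#'   [progression_screen()].
#' @return list of class \code{"cascade_report"} with per-contrast sets,
#'   counts, the shared FDR set, and (if supplied) the unidirectional
#'   breakdown.
#' @export
significance_cascade <- function(results, manifest, p_alpha = 0.05,
                                 fdr_alpha = 0.05, unidirectional = NULL) {
  need <- c("control_vs_NASH", "control_vs_HCC")
  if (!all(need %in% names(results))) {
    stop("results must be named and include ", paste(need, collapse = ", "))
  }
  universe <- results[[1L]]$marker_id
  for (nm in names(results)) {
    if (!setequal(results[[nm]]$marker_id, universe)) {
      d <- c(setdiff(results[[nm]]$marker_id, universe),
             setdiff(universe, results[[nm]]$marker_id))
      stop("marker universes differ across contrasts; symmetric difference: ",
           paste(utils::head(d, 5), collapse = ", "))
    }
  }
  sets <- lapply(results, function(r) list(
    p = r$marker_id[r$p_value < p_alpha],
    fdr = r$marker_id[r$q_value <= fdr_alpha]
  ))
  shared_fdr <- intersect(sets$control_vs_NASH$fdr, sets$control_vs_HCC$fdr)

  is_pep <- stats::setNames(manifest$is_peptide, manifest$marker_id)
  prot <- stats::setNames(manifest$protein, manifest$marker_id)
  split_class <- function(ids) list(
    glycopeptides = ids[!is_pep[ids]],
    peptides = ids[is_pep[ids]]
  )
  rep_ <- list(
    p_alpha = p_alpha, fdr_alpha = fdr_alpha,
    sets = sets,
    counts = lapply(sets, function(s) list(p = length(s$p),
                                           fdr = length(s$fdr))),
    shared_fdr = shared_fdr,
    shared_fdr_by_class = lapply(split_class(shared_fdr), length),
    shared_fdr_proteins = sort(unique(prot[shared_fdr]))
  )
  if (!is.null(unidirectional)) {
    uni <- intersect(unidirectional, shared_fdr)
    cls <- split_class(uni)
    rep_$unidirectional <- list(
      markers = uni,
      glycopeptides = cls$glycopeptides,
      peptides = cls$peptides,
      n_glycopeptides = length(cls$glycopeptides),
      n_peptides = length(cls$peptides),
      proteins = sort(unique(prot[cls$glycopeptides]))
    )
  }
  class(rep_) <- "cascade_report"
  rep_
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Significance cascade (p < ", x$p_alpha, ", FDR <= ", x$fdr_alpha,
      ")\n", sep = "")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s p-significant: %4d   FDR-significant: %4d\n",
                nm, x$counts[[nm]]$p, x$counts[[nm]]$fdr))
  }
  cat("  shared across control contrasts (FDR):", length(x$shared_fdr), "\n")
  if (!is.null(x$unidirectional)) {
    cat("  unidirectional progression markers:",
        x$unidirectional$n_glycopeptides, "glycopeptides +",
        x$unidirectional$n_peptides, "peptides from",
        length(x$unidirectional$proteins), "glycoproteins\n")
  }
  invisible(x)
}

#' Strict monotonicity predicate for adjusted group means
#'
#' @param means numeric(3): adjusted means for control, NASH, HCC (in that
#'   order).
#' @return \code{TRUE} iff strictly increasing or strictly decreasing.
#' @examples
#' unidirectional(c(1, 2, 3))  # TRUE
#' unidirectional(c(1, 3, 2))  # FALSE
#' @export
unidirectional <- function(means) {
  stopifnot(length(means) == 3L)
  all(diff(means) > 0) || all(diff(means) < 0)
}

#' Screen for unidirectional progression markers
#'
#' A marker is a progression marker when its covariate-adjusted phenotype
#' means change strictly monotonically across the cascade
#' control -> NASH -> HCC (either direction; ties fail) AND it is
#' FDR-significant in both control contrasts. Adjusted means come from one
#' least-squares fit per marker of log2(abundance) on the three-level
#' phenotype factor plus covariates, so monotonicity depends only on the
#' phenotype coefficients.
#'
#' @inheritParams adjusted_fold_change
#' @param markers optional candidate subset (default: all markers in
#'   \code{norm}).
#' @param fdr_alpha FDR level for the control contrasts (default 0.05).
#' @param phenotypes the ordered cascade labels.
#' @return data frame of class \code{"progression_screen"}: per candidate
#'   marker the three adjusted means (log2 scale), monotonicity flag, the
#'   two control-contrast q-values, and \code{passes}.
#' @export
progression_screen <- function(norm, sheet, markers = NULL,
                               covariates = c("age", "sex"),
                               fdr_alpha = 0.05,
                               phenotypes = c("control", "NASH", "HCC")) {
  x <- .abundance_values(norm)
  stopifnot(length(phenotypes) == 3L)
  if (!is.null(sheet$is_reference)) {
    sheet <- sheet[!sheet$is_reference, , drop = FALSE]
  }
  sheet <- sheet[sheet$phenotype %in% phenotypes, , drop = FALSE]
  present <- unique(sheet$phenotype)
  if (!all(phenotypes %in% present)) {
    stop("missing phenotype group(s): ",
         paste(setdiff(phenotypes, present), collapse = ", "))
  }
  if (is.null(markers)) markers <- rownames(x)
  x <- x[markers, , drop = FALSE]

  d_nash <- adjusted_fold_change(x, sheet, c(phenotypes[1L], phenotypes[2L]),
                                 covariates = covariates)
  d_hcc <- adjusted_fold_change(x, sheet, c(phenotypes[1L], phenotypes[3L]),
                                covariates = covariates)

  keep <- intersect(colnames(x), sheet$sample_id)
  sheet <- sheet[match(keep, sheet$sample_id), , drop = FALSE]
  xx <- x[, keep, drop = FALSE]
  ph <- factor(sheet$phenotype, levels = phenotypes)
  design <- stats::model.matrix(~ ph)
  colnames(design) <- c("(Intercept)", "nash", "hcc")
  if ("age" %in% covariates) design <- cbind(design, age = sheet$age)
  if ("sex" %in% covariates) {
    design <- cbind(design, sexM = as.numeric(sheet$sex == "M"))
  }
  qr0 <- qr(design)
  if (qr0$rank < ncol(design)) {
    keep_cols <- sort(qr0$pivot[seq_len(qr0$rank)])
    design <- design[, keep_cols, drop = FALSE]
    qr0 <- qr(design)
  }
  coefs <- qr.coef(qr0, t(log2(xx)))
  mu_c <- coefs["(Intercept)", ]
  mu_n <- mu_c + coefs["nash", ]
  mu_h <- mu_c + coefs["hcc", ]
  mono <- (coefs["nash", ] > 0 & coefs["hcc", ] > coefs["nash", ]) |
          (coefs["nash", ] < 0 & coefs["hcc", ] < coefs["nash", ])

  q1 <- d_nash$q_value[match(markers, d_nash$marker_id)]
  q2 <- d_hcc$q_value[match(markers, d_hcc$marker_id)]
  out <- data.frame(
    marker_id = markers,
    mean_control = mu_c, mean_nash = mu_n, mean_hcc = mu_h,
    monotone = as.logical(mono),
    q_control_vs_nash = q1, q_control_vs_hcc = q2,
    passes = as.logical(mono) & q1 <= fdr_alpha & q2 <= fdr_alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "fdr_alpha") <- fdr_alpha
  class(out) <- c("progression_screen", "data.frame")
  out
}

#' @export
print.progression_screen <- function(x, ...) {
  cat("Progression-marker screen: ", sum(x$passes), " of ", nrow(x),
      " markers unidirectional at FDR <= ", attr(x, "fdr_alpha"), "\n",
      sep = "")
  invisible(x)
}
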