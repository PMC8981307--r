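#' Default fucosylation-by-sialylation motif groups
#'
#' The six (Fuc, Sial) groups used for the motif-level view of the panel:
#' non-fucosylated glycoforms with 0, 3 or 4 sialic acids and
#' core-fucosylated glycoforms with 2, 3 or 4 sialic acids. Optional series
#' filters (fixed hexose/HexNAc, e.g. the 65xx series) can be produced with
#' \code{series = TRUE}, which appends per-series groups for the 54xx, 65xx
#' and 76xx code families.
#'
#' @param series also include the 54xx/65xx/76xx series groups.
#' @return data frame of motif group specs: \code{label}, \code{fucose},
#'   \code{sialic} (exact counts; NA = any), \code{hexose}, \code{hexnac}
#'   (series filters; NA = any).
#' @export
default_motif_groups <- function(series = FALSE) {
  g <- data.frame(
    label = c("0 Fuc, 0 Sial", "0 Fuc, 3 Sial", "0 Fuc, 4 Sial",
              "1 Fuc, 2 Sial", "1 Fuc, 3 Sial", "1 Fuc, 4 Sial"),
    fucose = c(0L, 0L, 0L, 1L, 1L, 1L),
    sialic = c(0L, 3L, 4L, 2L, 3L, 4L),
    hexose = NA_integer_, hexnac = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (series) {
    s <- data.frame(
      label = c("54xx series", "65xx series", "76xx series"),
      fucose = NA_integer_, sialic = NA_integer_,
      hexose = c(5L, 6L, 7L), hexnac = c(4L, 5L, 6L),
      stringsAsFactors = FALSE
    )
    g <- rbind(g, s)
  }
  g
}

#' Assign glycopeptide markers to motif groups
#'
#' Each marker's glycan composition is matched against the specs; a spec
#' field left NA matches any count. A marker matching two specs is an error
#' (the caller's group set must partition, or at least not overlap on, the
#' observed compositions); markers matching no spec are simply unassigned.
#'
#' @param manifest marker manifest; peptide rows are ignored.
#' @param specs motif group specs as from [default_motif_groups()].
#' @return list of class \code{"motif_membership"}: \code{members} (named
#'   list label -> marker ids) and \code{counts} (named integer vector).
#' @export
group_by_motif <- function(manifest, specs = default_motif_groups()) {
  glyco <- manifest[!manifest$is_peptide, , drop = FALSE]
  members <- stats::setNames(vector("list", nrow(specs)), specs$label)
  if (nrow(glyco)) {
    comp <- parse_glycan_code(glyco$glycan_code)
    match_spec <- function(s) {
      ok <- rep(TRUE, nrow(comp))
      for (f in c("fucose", "sialic", "hexose", "hexnac")) {
        if (!is.na(s[[f]])) ok <- ok & comp[[f]] == s[[f]]
      }
      ok
    }
    hit <- vapply(seq_len(nrow(specs)), function(i) match_spec(specs[i, ]),
                  logical(nrow(comp)))
    hit <- matrix(hit, nrow = nrow(comp))
    multi <- rowSums(hit) > 1L
    if (any(multi)) {
      stop("marker(s) match more than one motif group: ",
           paste(utils::head(glyco$marker_id[multi], 5), collapse = ", "))
    }
    for (i in seq_len(nrow(specs))) {
      members[[i]] <- glyco$marker_id[hit[, i]]
    }
  } else {
    members[] <- list(character(0))
  }
  out <- list(members = members,
              counts = vapply(members, length, integer(1)))
  class(out) <- "motif_membership"
  out
}

#' @export
print.motif_membership <- function(x, ...) {
  cat("Motif group membership:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %d markers\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Summarize cumulative motif-group relative abundance by phenotype
#'
#' Per sample, a group's value is the sum of its members' relative
#' abundances; group means are reported per phenotype, and each group is
#' tested against control with the same covariate-adjusted log2 least-squares
#' model used for individual markers, BH-corrected across groups within each
#' contrast.
#'
#' @param rel relative abundance matrix from [relative_abundance()].
#' @param membership a \code{motif_membership} from [group_by_motif()].
#' @param sheet sample sheet.
#' @param covariates covariates for the group-level tests.
#' @param phenotypes cascade order; the first is the control reference.
#' @return data frame of class \code{"motif_summary"}: one row per group x
#'   non-control phenotype with member count, per-phenotype means, fold
#'   change vs control, p and q. Attribute \code{"group_values"} carries the
#'   per-sample group sums (groups x samples).
#' @export
motif_abundance_summary <- function(rel, membership, sheet,
                                    covariates = c("age", "sex"),
                                    phenotypes = c("control", "NASH", "HCC")) {
  stopifnot(inherits(membership, "motif_membership"))
  x <- .abundance_values(rel)
  extra <- setdiff(unlist(membership$members), rownames(x))
  if (length(extra)) {
    stop("membership markers absent from relative abundance matrix: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  labels <- names(membership$members)
  gv <- matrix(0, nrow = length(labels), ncol = ncol(x),
               dimnames = list(labels, colnames(x)))
  for (i in seq_along(labels)) {
    ids <- membership$members[[i]]
    if (length(ids)) gv[i, ] <- colSums(x[ids, , drop = FALSE])
  }

  if (!is.null(sheet$is_reference)) {
    sheet <- sheet[!sheet$is_reference, , drop = FALSE]
  }
  keep <- intersect(colnames(gv), sheet$sample_id)
  sh <- sheet[match(keep, sheet$sample_id), , drop = FALSE]
  gvk <- gv[, keep, drop = FALSE]

  rows <- list()
  tested <- labels[membership$counts > 0L]
  means <- sapply(phenotypes, function(p) {
    cols <- sh$sample_id[sh$phenotype == p]
    if (length(cols)) rowMeans(gvk[, cols, drop = FALSE])
    else rep(NA_real_, nrow(gvk))
  })
  means <- matrix(means, nrow = nrow(gvk),
                  dimnames = list(labels, phenotypes))

  for (p in phenotypes[-1L]) {
    if (!any(sh$phenotype == p)) next
    dd <- if (length(tested)) {
      adjusted_fold_change(gvk[tested, , drop = FALSE] , sh,
                           contrast = c(p, phenotypes[1L]),
                           covariates = covariates)
    } else NULL
    for (lab in labels) {
      r <- data.frame(
        group = lab, phenotype = p,
        n_members = membership$counts[[lab]],
        mean_control = means[lab, phenotypes[1L]],
        mean_phenotype = means[lab, p],
        fold_vs_control = NA_real_, p_value = NA_real_, q_value = NA_real_,
        stringsAsFactors = FALSE
      )
      if (!is.null(dd) && lab %in% dd$marker_id) {
        j <- match(lab, dd$marker_id)
        r$fold_vs_control <- dd$fold_change[j]
        r$p_value <- dd$p_value[j]
        r$q_value <- dd$q_value[j]
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), phenotype = character(0),
               n_members = integer(0), mean_control = numeric(0),
               mean_phenotype = numeric(0), fold_vs_control = numeric(0),
               p_value = numeric(0), q_value = numeric(0))
  rownames(out) <- NULL
  attr(out, "group_values") <- gv
  attr(out, "phenotypes") <- phenotypes
  class(out) <- c("motif_summary", "data.frame")
  out
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("Motif-group relative abundance summary\n")
  print(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

#' Bar chart of motif-group means by phenotype
#'
#' @param x a \code{motif_summary}.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.motif_summary <- function(x, ...) {
  phen <- attr(x, "phenotypes")
  labs <- unique(x$group)
  h <- rbind(x$mean_control[match(labs, x$group)])
  for (p in phen[-1L]) {
    xp <- x[x$phenotype == p, ]
    h <- rbind(h, xp$mean_phenotype[match(labs, xp$group)])
  }
  rownames(h) <- phen
  graphics::barplot(h, beside = TRUE, names.arg = labs, las = 2,
                    legend.text = phen,
                    ylab = "cumulative relative abundance", ...)
  invisible(x)
}
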