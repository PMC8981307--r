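#' Parse 4-digit glycan composition codes
#'
#' Targeted serum glycoproteomics panels label each N-glycan by a compact
#' 4-digit composition code \code{[Hex][HexNAc][Fuc][Sia]}: the first digit
#' counts hexoses, the second N-acetyl-hexosamines, the third fucoses and the
#' fourth sialic acids. For example \code{"5402"} is a bi-antennary glycan
#' with five hexoses, four HexNAc, no fucose and two sialic acids.
#'
#' @param code character vector of 4-digit codes.
#' @return A data frame of class \code{"glycan_composition"} with one row per
#'   code and integer columns \code{hexose}, \code{hexnac}, \code{fucose},
#'   \code{sialic} plus the original \code{code}.
#' @examples
#' parse_glycan_code(c("5402", "6511"))
#' @seealso [format_glycan_code()], [classify_motif()]
#' @export
parse_glycan_code <- function(code) {
  if (length(code) == 0L) stop("no glycan code supplied")
  code <- as.character(code)
  bad <- is.na(code) | !grepl("^[0-9]{4}$", code)
  if (any(bad)) {
    stop("invalid glycan code(s): ",
         paste(sQuote(code[bad]), collapse = ", "),
         " (expected exactly four decimal digits)")
  }
  dig <- function(i) as.integer(substr(code, i, i))
  out <- data.frame(
    hexose = dig(1L), hexnac = dig(2L), fucose = dig(3L), sialic = dig(4L),
    code = code, stringsAsFactors = FALSE
  )
  class(out) <- c("glycan_composition", "data.frame")
  out
}

#' Format a glycan composition back to its 4-digit code
#'
#' Inverse of [parse_glycan_code()]: concatenates the four monosaccharide
#' counts into the canonical code string.
#'
#' @param comp a \code{glycan_composition} data frame (or any data frame with
#'   columns \code{hexose}, \code{hexnac}, \code{fucose}, \code{sialic}).
#' @return character vector of 4-digit codes.
#' @export
format_glycan_code <- function(comp) {
  cols <- c("hexose", "hexnac", "fucose", "sialic")
  if (!all(cols %in% names(comp))) {
    stop("composition must have columns ", paste(cols, collapse = ", "))
  }
  cnt <- as.matrix(comp[cols])
  if (any(cnt < 0L | cnt > 9L)) stop("monosaccharide counts must be in 0..9")
  paste0(cnt[, 1L], cnt[, 2L], cnt[, 3L], cnt[, 4L])
}

#' Classify a glycan composition into fucosylation/sialylation/branching motifs
#'
#' Derives the motif descriptors used throughout the analysis:
#' \code{fucosylated} (any fucose present; in serum N-glycomics by MRM the
#' fucose digit is dominated by core fucosylation), the sialylation count, and
#' antennarity inferred from the HexNAc count (4 = bi-, 5 = tri-,
#' 6 = tetra-antennary, anything else \code{"other"}).
#'
#' @param comp a \code{glycan_composition} data frame, or a character vector
#'   of codes (parsed on the fly).
#' @return data frame with columns \code{code}, \code{fucosylated} (logical),
#'   \code{sialylation_count} (integer), \code{antennarity} (factor with
#'   levels bi, tri, tetra, other).
#' @examples
#' classify_motif("6503")  # non-fucosylated, tri-antennary, 3 sialic acids
#' @export
classify_motif <- function(comp) {
  if (is.character(comp)) comp <- parse_glycan_code(comp)
  ant <- rep("other", nrow(comp))
  ant[comp$hexnac == 4L] <- "bi"
  ant[comp$hexnac == 5L] <- "tri"
  ant[comp$hexnac == 6L] <- "tetra"
  data.frame(
    code = comp$code,
    fucosylated = comp$fucose >= 1L,
    sialylation_count = comp$sialic,
    antennarity = factor(ant, levels = c("bi", "tri", "tetra", "other")),
    stringsAsFactors = FALSE
  )
}

# dashes accepted in marker ids: hyphen, en dash, em dash
.dash_rx <- "[-–—]"

#' Parse a glycopeptide marker identifier
#'
#' Marker identifiers follow the grammar
#' \code{"PROT (site[ and site2]) – code[ and code2]"} for glycopeptides
#' (e.g. \code{"A2MG (1424) – 5402"}, or with two glycosylation sites
#' \code{"HPT (207 and 211) – 5401 and 5402"}) and
#' \code{"PROT – PEPTIDESEQ"} for non-glycosylated peptide markers
#' (e.g. \code{"A2MG – AIGYLNTGYQR"}). Hyphen, en dash and em dash are
#' all accepted as the separator; the canonical form uses the en dash.
#'
#' @param text a single marker identifier string.
#' @return A list of class \code{"glyco_marker"} with elements
#'   \code{marker_id} (canonical form), \code{protein}, \code{sites}
#'   (integer vector, possibly empty), \code{glycans} (character vector of
#'   codes, or \code{NULL}), \code{peptide} (sequence or \code{NULL}) and
#'   \code{is_peptide}.
#' @examples
#' parse_marker_id("HPT (207 and 211) - 5401 and 5402")
#' @export
parse_marker_id <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("marker id must be a single non-empty string")
  }
  txt <- trimws(text)
  # split protein [ (sites) ] from payload at the dash
  rx_glyco <- paste0("^([A-Za-z0-9]+)\\s*\\(([0-9]+(?:\\s+and\\s+[0-9]+)*)\\)\\s*",
                     .dash_rx, "\\s*([0-9]{4}(?:\\s+and\\s+[0-9]{4})*)$")
  rx_pep <- paste0("^([A-Za-z0-9]+)\\s*", .dash_rx, "\\s*([A-Z]{2,})$")
  if (grepl(rx_glyco, txt)) {
    m <- regmatches(txt, regexec(rx_glyco, txt))[[1L]]
    protein <- m[2L]
    sites <- as.integer(strsplit(m[3L], "\\s+and\\s+")[[1L]])
    glycans <- strsplit(m[4L], "\\s+and\\s+")[[1L]]
    parse_glycan_code(glycans)  # validates
    marker <- list(protein = protein, sites = sites, glycans = glycans,
                   peptide = NULL, is_peptide = FALSE)
  } else if (grepl(rx_pep, txt)) {
    m <- regmatches(txt, regexec(rx_pep, txt))[[1L]]
    if (grepl("^[0-9]{4}$", m[3L])) stop("unreachable")
    marker <- list(protein = m[2L], sites = integer(0), glycans = NULL,
                   peptide = m[3L], is_peptide = TRUE)
  } else {
    # locate first structural deviation for the error message
    pos <- regexpr(paste0("\\s*", .dash_rx, "\\s*"), txt)
    stop("malformed marker id ", sQuote(text),
         if (pos < 0) " (no dash separator found)" else
           paste0(" (cannot parse segment after position ", pos, ")"))
  }
  marker$marker_id <- format_marker_id(marker)
  class(marker) <- "glyco_marker"
  marker
}

#' Format a marker to its canonical identifier
#'
#' @param marker a \code{glyco_marker} as returned by [parse_marker_id()], or
#'   a bare list with the same fields.
#' @return canonical identifier string (en-dash separator).
#' @export
format_marker_id <- function(marker) {
  if (isTRUE(marker$is_peptide)) {
    paste0(marker$protein, " – ", marker$peptide)
  } else {
    paste0(marker$protein,
           " (", paste(marker$sites, collapse = " and "), ") – ",
           paste(marker$glycans, collapse = " and "))
  }
}

#' @export
print.glyco_marker <- function(x, ...) {
  kind <- if (x$is_peptide) "peptide marker" else "glycopeptide marker"
  cat("<", kind, "> ", x$marker_id, "\n", sep = "")
  invisible(x)
}
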