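#' Metabolite concentration panel
#'
#' Per-sample amino-acid concentrations for one compartment: plasma
#' (micromolar) or fecal (nmol per gram). Analytes recorded as not detected
#' are stored as `NA` and excluded pairwise downstream rather than imputed
#' as zero.
#'
#' @param concentrations numeric matrix samples x analytes, with sample ids
#'   as rownames and analyte names (3-letter amino-acid codes) as colnames;
#'   `NA` marks not-detected values.
#' @param compartment `"plasma"` or `"fecal"`.
#' @return a `metabolite_panel` with elements `concentrations` and
#'   `compartment`.
#' @export
metabolite_panel <- function(concentrations,
                             compartment = c("plasma", "fecal")) {
  compartment <- match.arg(compartment)
  if (!is.matrix(concentrations) || !is.numeric(concentrations))
    stop("'concentrations' must be a numeric matrix (samples x analytes)")
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations)))
    stop("'concentrations' needs sample rownames and analyte colnames")
  if (anyDuplicated(rownames(concentrations)))
    stop("duplicate sample ids in metabolite panel")
  if (anyDuplicated(tolower(colnames(concentrations))))
    stop("duplicate analyte names in metabolite panel")
  v <- concentrations[!is.na(concentrations)]
  if (any(!is.finite(v)) || any(v < 0))
    stop("concentrations must be finite and >= 0 where present")
  structure(list(concentrations = concentrations, compartment = compartment),
            class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat("metabolite_panel (", x$compartment, "): ",
      nrow(x$concentrations), " samples x ",
      ncol(x$concentrations), " analytes; ",
      sum(is.na(x$concentrations)), " not detected\n", sep = "")
  invisible(x)
}

# case-insensitive 3-letter amino-acid codes used by derived panels
EAA_CODES <- c("His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr", "Trp", "Val")
BCAA_CODES <- c("Leu", "Ile", "Val")
AROMATIC_CODES <- c("Phe", "Tyr")

match_analytes <- function(panel, codes) {
  analytes <- colnames(panel$concentrations)
  idx <- match(tolower(codes), tolower(analytes))
  if (anyNA(idx))
    stop("metabolite panel lacks required amino acid(s): ",
         paste(codes[is.na(idx)], collapse = ", "))
  analytes[idx]
}

#' Derived amino-acid panels
#'
#' Computes, per sample: the total amino-acid concentration (sum over all
#' analytes in the panel), total essential amino acids (His + Ile + Leu +
#' Lys + Met + Phe + Thr + Trp + Val), total branched-chain amino acids
#' (Leu + Ile + Val), and Fischer's ratio, the ratio of BCAAs to the
#' aromatic amino acids Phe + Tyr — a clinical index of amino-acid
#' imbalance. Any missing (not-detected) component propagates `NA` to the
#' derived value; Fischer's ratio is also `NA` when Phe + Tyr is zero.
#'
#' @param panel a [metabolite_panel()] whose analytes cover at least the
#'   nine essential amino acids plus Tyr (matched case-insensitively by
#'   3-letter code).
#' @return data.frame with columns `sample_id`, `total_aa`, `total_eaa`,
#'   `total_bcaa`, `fischer_ratio`.
#' @examples
#' conc <- matrix(c(100, 50, 150, 50, 50), 1,
#'                dimnames = list("s1", c("Leu", "Ile", "Val", "Phe", "Tyr")))
#' # BCAA = 300, Fischer's ratio = 3 (panel lacking full EAA coverage errors)
#' @export
derive_panels <- function(panel) {
  stopifnot(inherits(panel, "metabolite_panel"))
  eaa <- match_analytes(panel, EAA_CODES)
  tyr <- match_analytes(panel, "Tyr")
  conc <- panel$concentrations
  bcaa_cols <- match_analytes(panel, BCAA_CODES)
  bcaa <- rowSums(conc[, bcaa_cols, drop = FALSE])
  arom <- rowSums(conc[, c(match_analytes(panel, "Phe"), tyr), drop = FALSE])
  fischer <- bcaa / arom
  fischer[!is.na(arom) & arom == 0] <- NA_real_
  data.frame(sample_id = rownames(conc),
             total_aa = rowSums(conc),
             total_eaa = rowSums(conc[, eaa, drop = FALSE]),
             total_bcaa = bcaa,
             fischer_ratio = fischer,
             row.names = NULL, stringsAsFactors = FALSE)
}
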