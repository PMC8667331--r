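#' Construct a KO abundance profile
#'
#' A `ko_profile` holds per-sample relative abundances (copies-per-million
#' scale) of KEGG Orthology (KO) gene families, optionally stratified by
#' genus. Features are rows, samples are columns, matching the layout of
#' HUMAnN2-style gene-family tables. Values are treated as relative
#' abundances; no renormalisation is performed, only validation.
#'
#' Stratified bookkeeping is conservative: the per-genus rows of a KO may
#' sum to less than the community row, and the remainder is attributed to an
#' implicit "unclassified" stratum (see [ko_strata()]). A stratified sum
#' exceeding the community value beyond relative tolerance `1e-6` is an
#' error.
#'
#' @param community numeric matrix of non-negative abundances with KO ids
#'   (`K` + 5 digits) as rownames and unique sample ids as colnames.
#' @param strata optional numeric matrix of genus-stratified abundances with
#'   rownames of the form `"K01652|g__Prevotella"` and the same columns as
#'   `community`, in the same order.
#' @return an object of class `ko_profile` with elements `community` and
#'   `strata` (possibly `NULL`).
#' @examples
#' m <- matrix(c(10, 20, 5, 0), 2, 2,
#'             dimnames = list(c("K00001", "K00002"), c("s1", "s2")))
#' p <- ko_profile(m)
#' n_kos(p)
#' @export
ko_profile <- function(community, strata = NULL) {
  if (!is.matrix(community) || !is.numeric(community))
    stop("'community' must be a numeric matrix (KOs x samples)")
  kos <- rownames(community) %||% character(0)
  samples <- colnames(community)
  if ((nrow(community) > 0 && length(kos) == 0) || is.null(samples))
    stop("'community' must have KO rownames and sample colnames")
  if (anyDuplicated(kos)) stop("duplicate KO ids in profile")
  if (anyDuplicated(samples)) stop("duplicate sample ids in profile")
  bad <- kos[!grepl("^K[0-9]{5}$", kos)]
  if (length(bad))
    stop("invalid KO ids (expected 'K' + 5 digits): ",
         paste(head(bad, 5), collapse = ", "))
  if (any(!is.finite(community)) || any(community < 0))
    stop("community abundances must be finite and >= 0")

  if (!is.null(strata)) {
    if (!is.matrix(strata) || !is.numeric(strata))
      stop("'strata' must be a numeric matrix")
    if (!identical(colnames(strata), samples))
      stop("strata columns must match community sample ids and order")
    sn <- rownames(strata)
    if (is.null(sn) || anyDuplicated(sn))
      stop("strata rows must have unique names 'KOxxxxx|g__Genus'")
    ok <- grepl("^K[0-9]{5}\\|g__[A-Za-z0-9_.-]+$", sn)
    if (any(!ok)) {
      deeper <- grepl("\\|[abcdefkops]__", sn[!ok])
      if (any(deeper))
        stop("stratified rows must be genus-level ('|g__'); found other ",
             "ranks: ", paste(head(sn[!ok][deeper], 3), collapse = ", "))
      stop("malformed strata row names: ",
           paste(head(sn[!ok], 5), collapse = ", "))
    }
    if (any(!is.finite(strata)) || any(strata < 0))
      stop("stratified abundances must be finite and >= 0")
    parents <- sub("\\|.*$", "", sn)
    orphan <- setdiff(unique(parents), kos)
    if (length(orphan))
      stop("stratified rows without a community row: ",
           paste(head(orphan, 5), collapse = ", "))
    ssum <- rowsum(strata, parents)
    comm <- community[rownames(ssum), , drop = FALSE]
    tol <- 1e-6 * pmax(comm, 1e-12)
    if (any(ssum > comm + tol))
      stop("stratified genus sums exceed community values beyond tolerance")
  }

  structure(list(community = community, strata = strata),
            class = "ko_profile")
}

#' @rdname ko_profile
#' @param x a `ko_profile`.
#' @export
n_kos <- function(x) nrow(x$community)

#' @rdname ko_profile
#' @export
n_samples <- function(x) ncol(x$community)

#' @rdname ko_profile
#' @export
sample_ids <- function(x) colnames(x$community)

#' @rdname ko_profile
#' @export
ko_ids <- function(x) rownames(x$community)

#' Genus strata of one KO
#'
#' Returns the per-genus abundance matrix of a KO, with an appended
#' `unclassified` row holding the community value minus the sum over genera
#' (clamped at zero), so that rows always add up to the community row.
#'
#' @param profile a [ko_profile()].
#' @param ko a single KO id.
#' @return numeric matrix genera x samples (rownames are bare genus names),
#'   or `NULL` if the KO has no stratified rows.
#' @export
ko_strata <- function(profile, ko) {
  stopifnot(inherits(profile, "ko_profile"), length(ko) == 1)
  if (!ko %in% ko_ids(profile)) stop("unknown KO: ", ko)
  if (is.null(profile$strata)) return(NULL)
  sn <- rownames(profile$strata)
  hit <- startsWith(sn, paste0(ko, "|"))
  if (!any(hit)) return(NULL)
  m <- profile$strata[hit, , drop = FALSE]
  rownames(m) <- sub("^.*\\|g__", "", rownames(m))
  uncl <- pmax(profile$community[ko, ] - colSums(m), 0)
  rbind(m, unclassified = uncl)
}

#' @export
print.ko_profile <- function(x, ...) {
  cat("ko_profile:", n_kos(x), "KOs x", n_samples(x), "samples")
  if (!is.null(x$strata))
    cat(";", nrow(x$strata), "genus-stratified rows")
  cat("\n")
  invisible(x)
}

# canonical row/column ordering, used by round-trip comparisons
sort_profile <- function(profile) {
  comm <- profile$community[order(rownames(profile$community)),
                            order(colnames(profile$community)),
                            drop = FALSE]
  strata <- profile$strata
  if (!is.null(strata))
    strata <- strata[order(rownames(strata)), colnames(comm), drop = FALSE]
  ko_profile(comm, strata)
}
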