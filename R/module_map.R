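#' Construct a KEGG module map
#'
#' Maps module ids (`M` + 5 digits) to their KO sets, annotated with the
#' amino acid the module acts on (`aa_target`, free text such as `"BCAA"`
#' or `"histidine"`, or `"other"`) and the module's metabolic role.
#'
#' @param module_id character vector of unique module ids.
#' @param kos list of non-empty character vectors of KO ids, one per module.
#' @param aa_target character vector of amino-acid targets (recycled).
#' @param role one of `"biosynthesis"`, `"degradation"`, `"transport"`,
#'   `"other"` per module (recycled).
#' @param label free-text module labels (recycled; defaults to the id).
#' @return a `module_map`: a data.frame with columns `module_id`,
#'   `aa_target`, `role`, `label` and list-column `kos`.
#' @examples
#' mm <- module_map("M00535", list(c("K01652", "K01653")),
#'                  aa_target = "BCAA", role = "biosynthesis")
#' @export
module_map <- function(module_id, kos, aa_target = "other", role = "other",
                       label = module_id) {
  module_id <- as.character(module_id)
  if (anyDuplicated(module_id))
    stop("duplicate module ids: ",
         paste(unique(module_id[duplicated(module_id)]), collapse = ", "))
  bad <- module_id[!grepl("^M[0-9]{5}$", module_id)]
  if (length(bad))
    stop("invalid module ids (expected 'M' + 5 digits): ",
         paste(head(bad, 5), collapse = ", "))
  if (!is.list(kos) || length(kos) != length(module_id))
    stop("'kos' must be a list of KO vectors, one per module")
  kos <- lapply(kos, function(k) unique(as.character(k)))
  if (any(lengths(kos) == 0))
    stop("every module needs a non-empty KO set")
  okko <- vapply(kos, function(k) all(grepl("^K[0-9]{5}$", k)), logical(1))
  if (any(!okko))
    stop("invalid KO ids in modules: ",
         paste(module_id[!okko], collapse = ", "))
  role <- match.arg(rep_len(as.character(role), length(module_id)),
                    c("biosynthesis", "degradation", "transport", "other"),
                    several.ok = TRUE)
  out <- data.frame(module_id = module_id,
                    aa_target = rep_len(as.character(aa_target),
                                        length(module_id)),
                    role = role,
                    label = rep_len(as.character(label), length(module_id)),
                    stringsAsFactors = FALSE)
  out$kos <- kos
  class(out) <- c("module_map", "data.frame")
  out
}

#' @export
print.module_map <- function(x, ...) {
  cat("module_map:", nrow(x), "modules,",
      length(unique(unlist(x$kos))), "distinct KOs\n")
  print.data.frame(cbind(x[, c("module_id", "aa_target", "role", "label")],
                         n_kos = lengths(x$kos)), ...)
  invisible(x)
}

#' Resolve a gene set from a module map
#'
#' A gene set can be named as a single module id (`"M00535"`), as
#' `"target/role"` (`"BCAA/biosynthesis"`, the union of all matching
#' modules' KOs), or given directly as a character vector of KO ids.
#'
#' @param map a [module_map()].
#' @param set module id, `"target/role"` key, or KO id vector.
#' @return character vector of KO ids.
#' @export
resolve_gene_set <- function(map, set) {
  stopifnot(inherits(map, "module_map"))
  if (length(set) > 1 || grepl("^K[0-9]{5}$", set[1]))
    return(unique(as.character(set)))
  if (grepl("^M[0-9]{5}$", set)) {
    i <- match(set, map$module_id)
    if (is.na(i)) stop("unknown module id: ", set)
    return(map$kos[[i]])
  }
  parts <- strsplit(set, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("gene set must be a module id, 'target/role' key, or KO vector: ",
         set)
  hit <- map$aa_target == parts[1] & map$role == parts[2]
  if (!any(hit)) stop("no modules match gene set key: ", set)
  unique(unlist(map$kos[hit]))
}
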