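# Tab-separated I/O for every external table the pipeline touches.
# All files are UTF-8, tab-separated, "." decimal; missing metabolite
# values are empty cells or "ND".

#' Read a (possibly stratified) KO gene-family table
#'
#' Expects a HUMAnN2-genefamilies-like dialect: a header row whose first
#' field names the feature column and whose remaining fields are sample
#' labels, then one row per feature. Community rows are bare KO ids
#' (`K01652`); genus-stratified rows are `K01652|g__Prevotella`.
#' Stratification below genus (e.g. `|s__`) is rejected. Feature rows that
#' match neither pattern are dropped with a warning that lists them.
#'
#' @param path path to a tab-separated table.
#' @return a [ko_profile()].
#' @export
read_ko_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("malformed header in ", path, ": need a feature column plus ",
         "at least one sample column")
  samples <- colnames(tab)[-1]
  feat <- as.character(tab[[1]])
  if (length(feat) == 0) {
    warning("no feature rows in ", path, "; returning an empty profile")
    comm <- matrix(numeric(0), 0, length(samples),
                   dimnames = list(character(0), samples))
    return(ko_profile(comm))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric abundance values in ", path)
  rownames(vals) <- feat

  deeper <- grepl("^K[0-9]{5}\\|", feat) &
    !grepl("^K[0-9]{5}\\|g__", feat)
  if (any(deeper))
    stop("stratified rows must be genus-level ('|g__'); found: ",
         paste(head(feat[deeper], 3), collapse = ", "))
  is_comm <- grepl("^K[0-9]{5}$", feat)
  is_strat <- grepl("^K[0-9]{5}\\|g__[A-Za-z0-9_.-]+$", feat)
  bad <- !(is_comm | is_strat)
  if (any(bad))
    warning(sum(bad), " feature row(s) rejected (not 'K'+5 digits): ",
            paste(head(feat[bad], 5), collapse = ", "))
  if (any(vals[!bad, ] < 0, na.rm = TRUE))
    stop("negative abundance values in ", path)

  comm <- vals[is_comm, , drop = FALSE]
  strata <- if (any(is_strat)) vals[is_strat, , drop = FALSE] else NULL
  if (nrow(comm) == 0 && is.null(strata))
    warning("no valid KO rows in ", path, "; returning an empty profile")
  ko_profile(comm, strata)
}

#' Write a KO profile
#'
#' Inverse of [read_ko_profile()]; community rows first, then stratified
#' rows. The implicit unclassified remainder is not written.
#'
#' @param profile a [ko_profile()].
#' @param path output path.
#' @export
write_ko_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ko_profile"))
  m <- profile$community
  if (!is.null(profile$strata)) m <- rbind(m, profile$strata)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module-map table
#'
#' Tab-separated columns: `module_id`, `aa_target`, `role`, comma-separated
#' `kos`, optional `label`.
#'
#' @param path path to the table.
#' @return a [module_map()].
#' @export
read_module_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("module_id", "aa_target", "role", "kos")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("module map ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  kos_str <- as.character(tab$kos)
  kos_str[is.na(kos_str)] <- ""
  kos <- strsplit(kos_str, ",", fixed = TRUE)
  kos <- lapply(kos, function(k) trimws(k[nzchar(trimws(k))]))
  label <- if ("label" %in% colnames(tab)) tab$label else tab$module_id
  module_map(tab$module_id, kos, aa_target = tab$aa_target,
             role = tab$role, label = label)
}

#' @rdname read_module_map
#' @param map a [module_map()].
#' @export
write_module_map <- function(map, path) {
  stopifnot(inherits(map, "module_map"))
  df <- data.frame(module_id = map$module_id, aa_target = map$aa_target,
                   role = map$role,
                   kos = vapply(map$kos, paste, "", collapse = ","),
                   label = map$label, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' Tab-separated columns `sample_id` and `group` (`case` / `control`).
#'
#' @param path path to the table.
#' @return a [cohort_design()].
#' @export
read_cohort_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(tab)))
    stop("metadata ", path, " needs columns 'sample_id' and 'group'")
  cohort_design(tab$sample_id, tab$group)
}

#' @rdname read_cohort_design
#' @param design a [cohort_design()].
#' @export
write_cohort_design <- function(design, path) {
  stopifnot(inherits(design, "cohort_design"))
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a metabolite concentration table
#'
#' Tab-separated; first column `sample_id`, remaining columns analytes.
#' Empty cells or `ND` mark not-detected values. The compartment is stored
#' in a leading `# compartment: <plasma|fecal>` comment line; when absent
#' it must be supplied via `compartment`.
#'
#' @param path path to the table.
#' @param compartment override / supply the compartment.
#' @return a [metabolite_panel()].
#' @export
read_metabolite_panel <- function(path, compartment = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# compartment:")) {
    found <- trimws(sub("^# compartment:", "", first))
    if (is.null(compartment)) compartment <- found
  }
  if (is.null(compartment))
    stop("compartment not recorded in ", path,
         " and not supplied; pass compartment = 'plasma' or 'fecal'")
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("", "NA", "ND"))
  if (!"sample_id" %in% colnames(tab))
    stop("metabolite table ", path, " needs a 'sample_id' column")
  m <- as.matrix(tab[, setdiff(colnames(tab), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$sample_id
  metabolite_panel(m, compartment)
}

#' @rdname read_metabolite_panel
#' @param panel a [metabolite_panel()].
#' @export
write_metabolite_panel <- function(panel, path) {
  stopifnot(inherits(panel, "metabolite_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# compartment:", panel$compartment), con)
  df <- data.frame(sample_id = rownames(panel$concentrations),
                   panel$concentrations, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "ND")
  invisible(path)
}
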