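# Plain-text readers and writers (TSV with '#' comments) and run
# configuration.  Columnar text matches the deposition formats of CD and
# SAXS repositories.

read_table_txt <- function(path, header = FALSE) {
  utils::read.table(path, header = header, sep = "", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a two-column spectrum file
#'
#' Expects numeric "wavelength intensity" rows; `#` comments allowed.
#' Wavelengths are sorted ascending if needed (with a warning).
#'
#' @param path File path.
#' @param role `"exp"` or `"calc"`.
#' @return A [spectrum].
#' @export
read_spectrum <- function(path, role = "exp") {
  tab <- tryCatch(read_table_txt(path),
                  error = function(e) stop("format error reading spectrum: ",
                                           conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 2 || nrow(tab) < 2)
    stop("format error: spectrum needs >= 2 rows of wavelength/intensity",
         call. = FALSE)
  wl <- as.numeric(tab[[1]]); I <- as.numeric(tab[[2]])
  if (anyNA(wl) || anyNA(I))
    stop("format error: non-numeric rows in spectrum", call. = FALSE)
  if (is.unsorted(wl, strictly = TRUE)) {
    warning("wavelengths not ascending; sorting")
    o <- order(wl); wl <- wl[o]; I <- I[o]
  }
  spectrum(wl, I, role = role)
}

#' Write a spectrum as two-column text
#' @param s A [spectrum].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  writeLines(c(sprintf("# wavelength_nm intensity_kMRE role=%s", s$role),
               sprintf("%.8g\t%.12g", s$wavelengths, s$I)), path)
  invisible(path)
}

#' Read a per-conformer prediction matrix
#'
#' Tabular text: header names the observables, first column holds unique
#' conformer ids, `NA` marks missing entries.
#'
#' @param path File path.
#' @return Numeric matrix (conformers x observables) with conformer ids as
#'   row names; missing entries are `NA`.
#' @export
read_matrix <- function(path) {
  tab <- read_table_txt(path, header = TRUE)
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate conformer id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a per-conformer matrix as TSV
#' @param m Numeric matrix with conformer row names (default `c1...cn`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("c", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("o", seq_len(ncol(m)))
  df <- data.frame(conformer_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read conformer weights ("conformer_id<TAB>weight")
#' @param path File path.
#' @return Named weight vector.
#' @export
read_weights <- function(path) {
  tab <- read_table_txt(path)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Write conformer weights as TSV
#' @param w Weight vector (or [weighted_ensemble]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  if (inherits(w, "weighted_ensemble")) {
    ids <- w$conformer_ids; w <- w$w
  } else ids <- if (is.null(names(w))) paste0("c", seq_along(w)) else names(w)
  writeLines(c("# conformer_id\tweight", sprintf("%s\t%.15g", ids, w)), path)
  invisible(path)
}

#' Read a basis-set file
#'
#' Header line of class names, then rows "wavelength v1 ... vK".
#'
#' @param path File path.
#' @return A [basis_set].
#' @export
read_basis_set <- function(path) {
  tab <- read_table_txt(path, header = TRUE)
  cls <- colnames(tab)[-1]
  basis_set(cls, as.numeric(tab[[1]]),
            t(as.matrix(tab[, -1, drop = FALSE])))
}

#' Write a basis set
#' @param basis A [basis_set].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_basis_set <- function(basis, path) {
  stopifnot(inherits(basis, "basis_set"))
  df <- data.frame(wavelength = basis$wavelengths, t(basis$B),
                   check.names = FALSE)
  colnames(df)[-1] <- basis$class_names
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SS composition ("class<TAB>fraction")
#' @param path File path.
#' @param scheme Scheme name to attach.
#' @param pure Enforce the unit-sum constraint.
#' @return An [ss_composition].
#' @export
read_ss_composition <- function(path, scheme, pure = TRUE) {
  tab <- read_table_txt(path)
  ss_composition(stats::setNames(as.numeric(tab[[2]]),
                                 as.character(tab[[1]])),
                 scheme = scheme, pure = pure)
}

#' Write an SS composition
#' @param comp An [ss_composition].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ss_composition <- function(comp, path) {
  stopifnot(inherits(comp, "ss_composition"))
  writeLines(sprintf("%s\t%.12g", names(comp$fractions), comp$fractions),
             path)
  invisible(path)
}

#' Write a theta-scan report as TSV
#' @param scan A `theta_scan`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a sub-ensemble member list ("conformer_id<TAB>multiplicity")
#' @param se A `subensemble`.
#' @param path File path.
#' @param conformer_ids Optional labels; default indices.
#' @return `path`, invisibly.
#' @export
write_subensemble <- function(se, path, conformer_ids = NULL) {
  stopifnot(inherits(se, "subensemble"))
  ids <- if (is.null(conformer_ids)) as.character(se$members$conformer)
         else conformer_ids[se$members$conformer]
  writeLines(c(sprintf("# size=%d replica=%d seed=%d",
                       se$size, se$replica_id, se$seed),
               sprintf("%s\t%d", ids, se$members$multiplicity)), path)
  invisible(path)
}

#' Load a run configuration
#'
#' YAML key-value file; unset keys fall back to the standard defaults
#' (theta grid `{0.1,1,2,5,10,20,50,100,200}`, CD uncertainty `delta =
#' 0.2`, `sigma0 = 0.75` kMRE, sub-ensemble sizes `{5,10,20,50,100,200}`
#' with 5 replicas, `frac = 0.5`, `improve_tol = 0.05`, `agree_tol = 1`,
#' `seed = 1`).  Any path-valued entry must point at an existing file.
#'
#' @param path YAML file path.
#' @return List of class `run_config` with all defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path))
      stop("config error: missing config file ", path, call. = FALSE)
    yaml::read_yaml(path)
  }
  defaults <- list(
    thetas = c(0.1, 1, 2, 5, 10, 20, 50, 100, 200),
    delta = 0.2, sigma0 = 0.75,
    sizes = c(5, 10, 20, 50, 100, 200), replicas = 5,
    frac = 0.5, improve_tol = 0.05, agree_tol = 1.0,
    seed = 1, outdir = ".")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg$thetas <- as.numeric(unlist(cfg$thetas))
  cfg$sizes <- as.numeric(unlist(cfg$sizes))
  if (any(cfg$thetas <= 0))
    stop("config error: theta grid must be positive", call. = FALSE)
  for (nm in grep("_file$", names(cfg), value = TRUE))
    if (!file.exists(cfg[[nm]]))
      stop("config error: missing file ", cfg[[nm]], call. = FALSE)
  structure(cfg, class = "run_config")
}
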