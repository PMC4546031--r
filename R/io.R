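# Plain-text spectrum I/O: two-column PRN files plus a CSV sample manifest.
# "PRN" is not a rigorous standard; we write tab-delimited and accept
# whitespace- or comma-delimited input.

#' Write one spectrum as a two-column PRN text file
#'
#' One point per line, wavenumber then absorbance, tab-delimited, descending
#' wavenumber, 12 significant digits (lossless round-trip at double
#' precision for spectroscopic magnitudes).
#'
#' @param grid Wavenumber grid (descending).
#' @param absorbance Absorbance vector aligned with `grid`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_prn <- function(grid, absorbance, path) {
  wn <- assert_grid(grid)
  if (length(absorbance) != length(wn)) {
    stop("`absorbance` length must match the grid length")
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("`absorbance` contains non-finite values; refusing to write")
  }
  writeLines(sprintf("%.12g\t%.12g", wn, absorbance), con = path)
  invisible(path)
}

#' Read a two-column PRN spectrum file
#'
#' Accepts whitespace- or comma-delimited numeric text, tolerating blank
#' lines and a single optional non-numeric header line. Ascending files are
#' re-ordered to the canonical descending wavenumber order with absorbances
#' permuted in lockstep.
#'
#' @param path Source file path.
#' @return A list with `grid` (descending numeric wavenumbers) and
#'   `absorbance`.
#' @export
read_prn <- function(path) {
  if (!file.exists(path)) stop("no such spectrum file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty spectrum file: ", path)
  parse_row <- function(s) {
    f <- strsplit(trimws(s), "[,[:space:]]+")[[1]]
    if (length(f) != 2L) return(NULL)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) return(NULL)
    v
  }
  rows <- lapply(lines, parse_row)
  bad <- which(vapply(rows, is.null, logical(1)))
  if (length(bad) > 0L && bad[1] == 1L) {
    # one optional header line
    rows <- rows[-1]; lines <- lines[-1]; lineno <- lineno[-1]
    bad <- which(vapply(rows, is.null, logical(1)))
  }
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric spectrum data at line %d of %s: '%s'",
                 lineno[bad[1]], path, lines[bad[1]]))
  }
  m <- do.call(rbind, rows)
  if (nrow(m) < 2L) stop("spectrum file has fewer than 2 points: ", path)
  if (anyDuplicated(m[, 1])) {
    stop("duplicate wavenumbers in spectrum file: ", path)
  }
  ord <- order(m[, 1], decreasing = TRUE)
  list(grid = m[ord, 1], absorbance = m[ord, 2])
}

#' Write a dataset as PRN spectra plus a CSV manifest
#'
#' Emits one PRN file per replicate spectrum (`<sample>_r<rep>.prn`) and a
#' `manifest.csv` with columns `sample_id`, `replicate_id`, `path`,
#' `igg_reference`, `kit`, `animal_class`. Paths in the manifest are
#' relative to its own directory.
#'
#' @param dataset An `atr_dataset` (see [simulate_dataset()]).
#' @param dir Output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep_tab <- dataset$replicates
  files <- sprintf("%s_r%d.prn", rep_tab$sample_id, rep_tab$replicate_id)
  for (i in seq_len(nrow(rep_tab))) {
    write_prn(dataset$grid, dataset$spectra[i, ], file.path(dir, files[i]))
  }
  manifest <- merge(
    data.frame(sample_id = rep_tab$sample_id,
               replicate_id = rep_tab$replicate_id,
               path = files, stringsAsFactors = FALSE),
    dataset$samples, by = "sample_id", sort = FALSE
  )
  manifest <- manifest[order(manifest$sample_id, manifest$replicate_id),
                       c("sample_id", "replicate_id", "path",
                         "igg_reference", "kit", "animal_class")]
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a CSV sample manifest and its referenced PRN spectra
#'
#' The manifest must carry columns `sample_id`, `replicate_id`, `path`,
#' `igg_reference`, `kit`, `animal_class`; `path` is resolved relative to
#' the manifest's directory unless absolute. Every referenced spectrum must
#' exist and share one wavenumber grid (within 1e-6 cm^-1). Replicate
#' counts that vary across samples produce a warning, not an error.
#'
#' @param path Manifest CSV path.
#' @return An `atr_dataset`-shaped list: `grid`, `samples`, `spectra`,
#'   `replicates`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate_id", "path", "igg_reference", "kit",
            "animal_class")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(path)
  files <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  absent <- !file.exists(files)
  if (any(absent)) {
    stop("manifest references missing spectrum file(s): ",
         paste(utils::head(files[absent], 3), collapse = ", "))
  }
  first <- read_prn(files[1])
  grid <- first$grid
  spectra <- matrix(NA_real_, nrow(man), length(grid))
  spectra[1, ] <- first$absorbance
  for (i in seq_len(nrow(man))[-1]) {
    s <- read_prn(files[i])
    if (length(s$grid) != length(grid) ||
        max(abs(s$grid - grid)) > 1e-6) {
      stop("spectrum grid mismatch across manifest files: ", files[i])
    }
    spectra[i, ] <- s$absorbance
  }
  rownames(spectra) <- paste0(man$sample_id, "_r", man$replicate_id)
  counts <- table(man$sample_id)
  if (length(unique(as.integer(counts))) > 1L) {
    warning("replicate count varies across samples in the manifest")
  }
  samples <- unique(man[, c("sample_id", "animal_class", "igg_reference",
                            "kit")])
  rownames(samples) <- NULL
  structure(list(
    grid = structure(grid, class = "wn_grid",
                     spacing = abs(grid[1] - grid[2])),
    samples = samples,
    spectra = spectra,
    replicates = data.frame(sample_id = man$sample_id,
                            replicate_id = man$replicate_id,
                            outlier_truth = NA, stringsAsFactors = FALSE)
  ), class = "atr_dataset")
}
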