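IMG_SIZE <- 128L

#' Construct a peak list
#'
#' A peak list is a tibble of HSQC cross-peaks with columns `h_shift`
#' (1H ppm), `c_shift` (13C ppm), `phase` (`"positive"`, `"negative"` or
#' `"unknown"`; the multiplicity-edited sign, CH/CH3 positive, CH2
#' negative) and `intensity` (non-negative relative amplitude), plus
#' metadata attributes `edited`, `solvent` and `source_id`. When `edited`
#' is `FALSE` the phases are ignored downstream.
#'
#' @param h_shift,c_shift numeric ppm coordinates (finite).
#' @param phase character vector, recycled.
#' @param intensity non-negative numeric, recycled.
#' @param edited logical: multiplicity-edited spectrum?
#' @param solvent,source_id optional metadata strings.
#' @return a `peak_list` tibble.
#' @export
#' @examples
#' peak_list(h_shift = c(6.30, 6.19), c_shift = c(92.9, 97.8))
peak_list <- function(h_shift = numeric(), c_shift = numeric(),
                      phase = "unknown", intensity = 1,
                      edited = FALSE, solvent = NULL, source_id = NULL) {
  n <- length(h_shift)
  if (length(c_shift) != n) abort("h_shift and c_shift lengths differ")
  if (n > 0 && !all(is.finite(h_shift) & is.finite(c_shift))) {
    abort("chemical shifts must be finite")
  }
  phase <- rep_len(as.character(phase), n)
  if (n > 0 && !all(phase %in% c("positive", "negative", "unknown"))) {
    abort("phase must be positive, negative or unknown")
  }
  intensity <- rep_len(as.numeric(intensity), n)
  if (n > 0 && any(!is.finite(intensity) | intensity < 0)) {
    abort("intensity must be finite and >= 0")
  }
  out <- tibble(
    h_shift = as.numeric(h_shift), c_shift = as.numeric(c_shift),
    phase = phase, intensity = intensity
  )
  structure(
    out,
    edited = isTRUE(edited), solvent = solvent, source_id = source_id,
    class = c("peak_list", class(out))
  )
}

#' @rdname peak_list
#' @param x data frame with at least `h_shift` and `c_shift` columns.
#' @export
as_peak_list <- function(x, edited = FALSE, solvent = NULL, source_id = NULL) {
  x <- as_tibble(x)
  peak_list(
    h_shift = x$h_shift, c_shift = x$c_shift,
    phase = if ("phase" %in% names(x)) x$phase else "unknown",
    intensity = if ("intensity" %in% names(x)) x$intensity else 1,
    edited = edited, solvent = solvent, source_id = source_id
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf(
    "<peak_list> %d peaks, %s HSQC%s\n", nrow(x),
    if (isTRUE(attr(x, "edited"))) "multiplicity-edited" else "normal",
    if (!is.null(attr(x, "source_id"))) paste0(" [", attr(x, "source_id"), "]") else ""
  ))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Is a peak list multiplicity-edited?
#' @param pl a `peak_list`.
#' @return logical scalar.
#' @export
is_edited <- function(pl) isTRUE(attr(pl, "edited"))

.parse_phase <- function(tok) {
  tok <- toupper(trimws(tok))
  dplyr::case_when(
    tok %in% c("+1", "1", "+", "P", "POS", "POSITIVE", "CH", "CH3") ~ "positive",
    tok %in% c("-1", "-", "N", "NEG", "NEGATIVE", "CH2") ~ "negative",
    tok %in% c("0", "?", "", "U", "UNK", "UNKNOWN", "NA") ~ "unknown",
    TRUE ~ NA_character_
  )
}

#' Parse a delimited HSQC peak table
#'
#' Accepts TSV/CSV/whitespace-delimited text with two to four columns:
#' 1H shift (ppm), 13C shift (ppm), optional phase (`+1`/`-1`, `CH`/`CH3`
#' vs `CH2`, or words), optional intensity. Lines starting with `#` and
#' blank lines are skipped; a single leading non-numeric header row is
#' allowed. Empty input yields an empty peak list.
#'
#' @param text character scalar (possibly multi-line) or vector of lines.
#' @param edited logical: is this a multiplicity-edited spectrum?
#' @param source_id optional identifier attached to the result.
#' @return a [peak_list()].
#' @export
#' @examples
#' parse_peak_table("6.30\t92.9\n6.19\t97.8")
parse_peak_table <- function(text, edited = FALSE, source_id = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(peak_list(edited = edited, source_id = source_id))
  }
  fields <- strsplit(trimws(lines[idx]), "[,;\t ]+")
  first <- fields[[1]]
  header <- length(first) >= 2 &&
    (is.na(suppressWarnings(as.numeric(first[1]))) ||
       is.na(suppressWarnings(as.numeric(first[2]))))
  if (header) {
    fields <- fields[-1]
    idx <- idx[-1]
  }
  if (length(fields) == 0) {
    return(peak_list(edited = edited, source_id = source_id))
  }
  n <- length(fields)
  h <- c_ <- inten <- numeric(n)
  ph <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 2) {
      abort(sprintf("line %d: expected at least 2 columns", idx[i]))
    }
    hv <- suppressWarnings(as.numeric(f[1]))
    cv <- suppressWarnings(as.numeric(f[2]))
    if (is.na(hv) || is.na(cv)) {
      abort(sprintf("line %d: malformed numeric field in '%s'", idx[i], lines[idx[i]]))
    }
    h[i] <- hv; c_[i] <- cv
    ph[i] <- if (length(f) >= 3) {
      p <- .parse_phase(f[3])
      if (is.na(p)) abort(sprintf("line %d: unrecognized phase '%s'", idx[i], f[3]))
      p
    } else "unknown"
    inten[i] <- if (length(f) >= 4) {
      v <- suppressWarnings(as.numeric(f[4]))
      if (is.na(v)) abort(sprintf("line %d: malformed intensity '%s'", idx[i], f[4]))
      v
    } else 1
  }
  peak_list(h, c_, ph, inten, edited = edited, source_id = source_id)
}

#' @rdname parse_peak_table
#' @param file path to a peak-table file.
#' @export
read_peaks <- function(file, edited = FALSE) {
  parse_peak_table(
    readLines(file, warn = FALSE), edited = edited,
    source_id = basename(file)
  )
}

#' Serialize a peak list back to tab-separated text
#'
#' Columns `h_shift`, `c_shift`, phase as `+1`/`-1`/`0`, intensity.
#' Shifts survive a parse round-trip to the printed precision.
#'
#' @param pl a `peak_list`.
#' @return character scalar of TSV text (with header).
#' @export
format_peak_table <- function(pl) {
  ph <- c(positive = "+1", negative = "-1", unknown = "0")[pl$phase]
  paste(
    c("H_ppm\tC_ppm\tphase\tintensity",
      sprintf("%.6g\t%.6g\t%s\t%.6g", pl$h_shift, pl$c_shift, ph, pl$intensity)),
    collapse = "\n"
  )
}

#' @rdname format_peak_table
#' @param file output path.
#' @export
write_peaks <- function(pl, file) {
  writeLines(format_peak_table(pl), file)
  invisible(file)
}

#' Remove one peak from a peak list
#'
#' @param pl a `peak_list`.
#' @param index 1-based peak index.
#' @return a new `peak_list` without the indexed peak.
#' @export
remove_peak <- function(pl, index) {
  n <- nrow(pl)
  if (length(index) != 1 || is.na(index) || index < 1 || index > n) {
    abort(sprintf("peak index must be in [1, %d]", n))
  }
  keep <- setdiff(seq_len(n), as.integer(index))
  as_peak_list(
    as_tibble(pl)[keep, , drop = FALSE],
    edited = is_edited(pl), solvent = attr(pl, "solvent"),
    source_id = attr(pl, "source_id")
  )
}

#' Spectrum bounds for rasterization
#'
#' Fixed ppm frame shared by all spectra so that images are comparable
#' across compounds. The defaults (1H 0--12.8 ppm, 13C 0--230 ppm) cover
#' the chemical shifts of typical natural products, including aldehydes
#' near 207.6/9.73 ppm.
#'
#' @param h_min,h_max,c_min,c_max ppm limits.
#' @return a `spectrum_bounds` list.
#' @export
spectrum_bounds <- function(h_min = 0, h_max = 12.8, c_min = 0, c_max = 230) {
  if (!(h_min < h_max) || !(c_min < c_max)) {
    abort("bounds require h_min < h_max and c_min < c_max")
  }
  structure(
    list(h_min = h_min, h_max = h_max, c_min = c_min, c_max = c_max),
    class = "spectrum_bounds"
  )
}

#' @export
print.spectrum_bounds <- function(x, ...) {
  cat(sprintf(
    "<spectrum_bounds> 1H [%g, %g] ppm, 13C [%g, %g] ppm\n",
    x$h_min, x$h_max, x$c_min, x$c_max
  ))
  invisible(x)
}

# Map shifts to 0-based pixel indices: high ppm at row/col 0 (conventional
# spectrum display), clamped to the frame.
.pixel_index <- function(shift, lo, hi) {
  i <- floor(IMG_SIZE * (hi - shift) / (hi - lo))
  pmin(pmax(i, 0), IMG_SIZE - 1L)
}

#' Rasterize a peak list to a fixed-geometry HSQC image
#'
#' Peaks become single-pixel impulses on a 128 x 128 grid (rows = 13C,
#' columns = 1H, high ppm at the top-left); several peaks on one pixel
#' combine by maximum. Normal spectra give one channel; multiplicity-edited
#' spectra give two (channel 1: positive or unknown phase, channel 2:
#' negative). Intensities are clipped at `intensity_cap` and rescaled to
#' \[0,1\] only when they exceed 1, so already-relative amplitudes pass
#' through unchanged. An optional Gaussian blur (sd in pixels) spreads
#' each impulse.
#'
#' @param pl a `peak_list`.
#' @param bounds a [spectrum_bounds()].
#' @param intensity_cap clip intensities above this value before scaling.
#' @param blur_sigma Gaussian blur sd in pixels (0 = impulse rendering).
#' @return an `hsqc_image`: list with `grid` (128 x 128 x C array),
#'   `bounds`, `edited`.
#' @export
#' @examples
#' img <- rasterize(peak_list(6.30, 92.9))
#' which(img$grid[, , 1] > 0, arr.ind = TRUE) # row 77, col 66 (1-based)
rasterize <- function(pl, bounds = spectrum_bounds(),
                      intensity_cap = Inf, blur_sigma = 0) {
  stopifnot(inherits(bounds, "spectrum_bounds"))
  edited <- is_edited(pl)
  nch <- if (edited) 2L else 1L
  grid <- array(0, dim = c(IMG_SIZE, IMG_SIZE, nch))
  if (nrow(pl) > 0) {
    inten <- pmin(pl$intensity, intensity_cap)
    m <- max(inten)
    if (m > 1) inten <- inten / m
    row <- .pixel_index(pl$c_shift, bounds$c_min, bounds$c_max) + 1L
    col <- .pixel_index(pl$h_shift, bounds$h_min, bounds$h_max) + 1L
    ch <- if (edited) ifelse(pl$phase == "negative", 2L, 1L) else 1L
    ch <- rep_len(ch, nrow(pl))
    for (i in seq_len(nrow(pl))) {
      grid[row[i], col[i], ch[i]] <- max(grid[row[i], col[i], ch[i]], inten[i])
    }
  }
  if (blur_sigma > 0) {
    for (c_ in seq_len(nch)) {
      grid[, , c_] <- .gauss_blur(grid[, , c_], blur_sigma)
    }
  }
  structure(
    list(grid = grid, bounds = bounds, edited = edited),
    class = "hsqc_image"
  )
}

# Separable Gaussian blur with a truncated (3 sd) normalized kernel.
.gauss_blur <- function(mat, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(mat)
  pad <- matrix(0, n + 2 * r, n + 2 * r)
  pad[(r + 1):(r + n), (r + 1):(r + n)] <- mat
  tmp <- matrix(0, n, n + 2 * r)
  for (j in seq_len(ncol(pad))) {
    tmp[, j] <- as.vector(stats::filter(pad[, j], k, sides = 2))[(r + 1):(r + n)]
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    out[i, ] <- as.vector(stats::filter(tmp[i, ], k, sides = 2))[(r + 1):(r + n)]
  }
  out
}

#' @export
print.hsqc_image <- function(x, ...) {
  cat(sprintf(
    "<hsqc_image> %d x %d x %d, %d nonzero cells, %s\n",
    dim(x$grid)[1], dim(x$grid)[2], dim(x$grid)[3],
    sum(x$grid != 0),
    if (x$edited) "edited" else "normal"
  ))
  invisible(x)
}
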