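#' Spot geometry of a printed microarray
#'
#' Describes the printed spot layout of a spatially barcoded microarray:
#' spot diameter, center-to-center pitch and the printable area. The default
#' values reproduce the cardiac array used throughout this package: 100 um
#' spots at 200 um pitch within a 6,200 x 6,600 um area.
#'
#' @param diameter Spot diameter in micrometers.
#' @param pitch Center-to-center spacing in micrometers; must be >= diameter.
#' @param width,height Printable area bounds in micrometers.
#' @return An object of class `spot_geometry`.
#' @export
spot_geometry <- function(diameter = 100, pitch = 200,
                          width = 6200, height = 6600) {
  if (!is.numeric(diameter) || diameter <= 0)
    stop("invalid geometry: diameter must be > 0", call. = FALSE)
  if (!is.numeric(pitch) || pitch < diameter)
    stop("invalid geometry: pitch must be >= diameter", call. = FALSE)
  if (width <= 0 || height <= 0)
    stop("invalid geometry: bounds must be positive", call. = FALSE)
  structure(list(diameter = diameter, pitch = pitch,
                 width = width, height = height),
            class = "spot_geometry")
}

#' @export
print.spot_geometry <- function(x, ...) {
  cat(sprintf("spot_geometry: %g um spots at %g um pitch in %g x %g um\n",
              x$diameter, x$pitch, x$width, x$height))
  invisible(x)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Concrete sequence space of a degenerate IUPAC template
#'
#' Expands a degenerate template such as the molecular-identifier slot
#' `"WSNNWSNNV"` into (i) a membership test for concrete sequences and
#' (ii) the number of concrete sequences it denotes (the product of the
#' per-position alphabet sizes).
#'
#' @param template A string over IUPAC nucleotide codes.
#' @return A list with elements `matcher` (function of one sequence,
#'   returning `TRUE`/`FALSE`), `cardinality` (a count), and `sets`
#'   (the per-position alphabets).
#' @examples
#' iupac_space("WSNNWSNNV")$cardinality  # 12288
#' @export
iupac_space <- function(template) {
  chars <- strsplit(toupper(template), "")[[1]]
  unknown <- setdiff(chars, names(IUPAC_SETS))
  if (length(unknown) > 0)
    stop("unknown IUPAC code(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  sets <- IUPAC_SETS[chars]
  card <- prod(vapply(sets, length, integer(1)))
  matcher <- function(seq) {
    s <- strsplit(toupper(seq), "")[[1]]
    if (length(s) != length(sets)) return(FALSE)
    all(mapply(function(base, set) base %in% set, s, sets))
  }
  list(matcher = matcher, cardinality = card, sets = sets)
}

#' Draw sequences uniformly from a degenerate template space
#'
#' @param template IUPAC template string.
#' @param n Number of sequences to draw (with replacement).
#' @return Character vector of concrete sequences.
#' @keywords internal
iupac_draw <- function(template, n) {
  sets <- iupac_space(template)$sets
  cols <- lapply(sets, function(set)
    set[sample.int(length(set), n, replace = TRUE)])
  do.call(paste0, cols)
}

#' Decode 1-based indices into a degenerate template space
#'
#' Maps integers `1..cardinality` bijectively onto the concrete sequences of
#' the template via mixed-radix decoding; used to draw molecular identifiers
#' without replacement.
#'
#' @param template IUPAC template string.
#' @param idx Integer vector of indices in `1..cardinality`.
#' @return Character vector of concrete sequences.
#' @keywords internal
iupac_decode <- function(template, idx) {
  sets <- iupac_space(template)$sets
  sizes <- vapply(sets, length, integer(1))
  card <- prod(sizes)
  if (any(idx < 1 | idx > card)) stop("index out of template space")
  rem <- idx - 1L
  out <- matrix("", nrow = length(idx), ncol = length(sets))
  for (p in rev(seq_along(sets))) {
    digit <- rem %% sizes[p]
    rem <- rem %/% sizes[p]
    out[, p] <- sets[[p]][digit + 1L]
  }
  apply(out, 1, paste0, collapse = "")
}

#' Generate a set of well-separated DNA barcodes
#'
#' Rejection-samples random DNA sequences until `n` barcodes with pairwise
#' Hamming distance at least `min_hamming` are collected. A minimum distance
#' of 3 keeps single-base sequencing errors from converting one barcode into
#' another, so that exact-match demultiplexing discards, rather than
#' misassigns, barcode-error reads.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nucleotides (default 18).
#' @param min_hamming Minimum pairwise Hamming distance (default 3).
#' @param seed Integer seed; the set is deterministic given the seed.
#' @param max_tries Attempt budget before declaring the request infeasible.
#' @return Character vector of `n` distinct barcodes.
#' @export
generate_barcodes <- function(n, length = 18, min_hamming = 3, seed = 1,
                              max_tries = 1000 * n) {
  stopifnot(n >= 1, length >= 1, min_hamming >= 1)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    acc <- matrix(NA_integer_, nrow = n, ncol = length)
    k <- 0L
    tries <- 0L
    while (k < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop(sprintf(
          "infeasible barcode request: %d barcodes of length %d at Hamming >= %d (gave up after %d tries)",
          n, length, min_hamming, max_tries), call. = FALSE)
      cand <- sample.int(4L, length, replace = TRUE)
      if (k > 0L) {
        d <- rowSums(acc[seq_len(k), , drop = FALSE] !=
                       matrix(cand, nrow = k, ncol = length, byrow = TRUE))
        if (any(d < min_hamming)) next
      }
      k <- k + 1L
      acc[k, ] <- cand
    }
    apply(acc, 1, function(r) paste0(bases[r], collapse = ""))
  })
}

# Perimeter walk (clockwise from top-left) of a rectangular ring of grid
# cells spanning columns c0..c1 and rows r0..r1; returns a matrix of
# (col, row) pairs.
ring_positions <- function(c0, c1, r0, r1) {
  top    <- cbind(c0:c1, r0)
  right  <- if (r1 > r0) cbind(c1, (r0 + 1):r1) else NULL
  bottom <- if (r1 > r0 && c1 > c0) cbind((c1 - 1):c0, r1) else NULL
  left   <- if (c1 > c0 && r1 - 1 > r0) cbind(c0, (r1 - 1):(r0 + 1)) else NULL
  ring <- rbind(top, right, bottom, left)
  colnames(ring) <- c("col", "row")
  ring
}

#' Generate a spatially barcoded array layout
#'
#' Places `n_features` barcoded capture spots on a regular rectangular grid
#' at the geometry's pitch (row-major feature ids, 1-based grid coordinates,
#' origin at the array top-left with y increasing downward), assigns each a
#' distinct 18-nt spatial barcode, and surrounds the feature block with
#' `n_frame` non-capturing frame spots used for image orientation. Frame
#' spots sit on grid positions of a rectangular ring chosen just wide enough
#' to hold them, so no two spots of any kind are closer than the pitch.
#'
#' @param geometry A [spot_geometry()].
#' @param n_features Number of barcoded features (default 1007).
#' @param n_frame Number of frame spots (default 148).
#' @param seed Integer seed for barcode generation.
#' @param barcode_length,min_hamming Barcode set parameters.
#' @return An object of class `array_layout` with elements `features`
#'   (data.frame: feature_id, barcode, x, y, grid_col, grid_row),
#'   `frame_spots` (data.frame: x, y), and `geometry`.
#' @examples
#' layout <- generate_layout(spot_geometry(), n_features = 1007, n_frame = 148)
#' nrow(layout$features)     # 1007
#' nrow(layout$frame_spots)  # 148
#' @export
generate_layout <- function(geometry = spot_geometry(), n_features = 1007,
                            n_frame = 148, seed = 1,
                            barcode_length = 18, min_hamming = 3) {
  stopifnot(inherits(geometry, "spot_geometry"))
  if (n_features < 1) stop("n_features must be >= 1", call. = FALSE)
  pitch <- geometry$pitch
  r <- geometry$diameter / 2
  ncols <- floor((geometry$width - geometry$diameter) / pitch) + 1
  nrows <- floor((geometry$height - geometry$diameter) / pitch) + 1
  if (ncols * nrows < n_features)
    stop(sprintf("capacity error: grid holds %d spots, %d requested",
                 ncols * nrows, n_features), call. = FALSE)
  idx <- seq_len(n_features) - 1L
  grid_col <- idx %% ncols + 1L
  grid_row <- idx %/% ncols + 1L
  features <- data.frame(
    feature_id = seq_len(n_features),
    barcode = generate_barcodes(n_features, barcode_length, min_hamming, seed),
    x = r + (grid_col - 1L) * pitch,
    y = r + (grid_row - 1L) * pitch,
    grid_col = grid_col,
    grid_row = grid_row,
    stringsAsFactors = FALSE
  )

  frame_spots <- data.frame(x = numeric(0), y = numeric(0))
  if (n_frame > 0) {
    used_cols <- max(grid_col)
    used_rows <- max(grid_row)
    # smallest ring margin (in pitch units) whose perimeter holds n_frame
    m <- 1L
    repeat {
      ring <- ring_positions(1L - m, used_cols + m, 1L - m, used_rows + m)
      if (nrow(ring) >= n_frame) break
      m <- m + 1L
    }
    take <- floor(seq(0, nrow(ring), length.out = n_frame + 1))[seq_len(n_frame)] + 1L
    ring <- ring[take, , drop = FALSE]
    frame_spots <- data.frame(
      x = r + (ring[, "col"] - 1L) * pitch,
      y = r + (ring[, "row"] - 1L) * pitch
    )
  }

  structure(list(features = features, frame_spots = frame_spots,
                 geometry = geometry),
            class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("array_layout: %d barcoded features + %d frame spots (%g um pitch)\n",
              nrow(x$features), nrow(x$frame_spots), x$geometry$pitch))
  invisible(x)
}

#' Write the barcode reference table of a layout
#'
#' Emits the file the demultiplexer consumes: one record per barcoded
#' feature with columns `barcode`, `x`, `y` (tab-separated, no header).
#'
#' @param layout An `array_layout`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_barcode_reference <- function(layout, path) {
  stopifnot(inherits(layout, "array_layout"))
  f <- layout$features
  if (anyDuplicated(f$barcode))
    stop("duplicate barcodes in layout; reference would be ambiguous",
         call. = FALSE)
  utils::write.table(f[, c("barcode", "x", "y")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a barcode reference table
#'
#' @param path Path to a tab-separated `barcode x y` file without header.
#' @return data.frame with columns `barcode`, `x`, `y` and an implied
#'   `feature_id` equal to the record number.
#' @export
read_barcode_reference <- function(path) {
  ref <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("barcode", "x", "y"),
                           colClasses = c("character", "numeric", "numeric"))
  if (anyDuplicated(ref$barcode))
    stop("malformed reference: duplicate barcodes", call. = FALSE)
  ref$feature_id <- seq_len(nrow(ref))
  ref
}

#' Tissue sections of the emulated cardiac biopsy study
#'
#' The study design this package's simulator emulates: ten adjacent tissue
#' sections — left-ventricle (LV) and right-atrial-appendage (RAA) biopsies
#' from three subjects with heart failure with preserved ejection fraction —
#' each placed on a 1,007-feature barcoded array, with the number of array
#' features covered by tissue in each section. Summing the per-section
#' counts gives the study's total number of spatially resolved tissue
#' domains.
#'
#' @return data.frame with columns `section`, `subject`, `region`
#'   (LV or RAA) and `features_under_tissue`.
#' @export
heart_sections <- function() {
  data.frame(
    section = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
    subject = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L),
    region  = c("LV", "LV", "RAA", "RAA", "LV", "LV",
                "LV", "LV", "RAA", "RAA"),
    features_under_tissue = c(61L, 60L, 282L, 292L, 55L, 52L,
                              107L, 85L, 534L, 365L),
    stringsAsFactors = FALSE
  )
}
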