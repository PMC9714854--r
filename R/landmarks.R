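#' Ordered, labeled 3D landmark set
#'
#' Landmarks are the unit of correspondence: two sets are comparable iff they
#' have the same length and the same label order. Coordinates are stored in
#' the package's internal RAS frame, in mm.
#'
#' @param coords numeric matrix, L x 3 (mm).
#' @param labels character vector of unique landmark names, length L. Defaults
#'   to `"lm1" ... "lmL"`.
#' @param frame coordinate frame tag of `coords`; `"RAS"` (internal) or
#'   `"LPS"` (converted on construction by negating x and y).
#' @param specimen specimen identifier.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(coords, labels = NULL, frame = c("RAS", "LPS"),
                         specimen = "specimen") {
  frame <- match.arg(frame)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3 || nrow(coords) < 1)
    stopf("landmark coordinates must be an L x 3 matrix with L >= 1")
  if (!all(is.finite(coords)))
    stopf("landmark set '%s': non-finite coordinates", specimen)
  if (frame == "LPS") coords[, 1:2] <- -coords[, 1:2]
  labels <- labels %||% paste0("lm", seq_len(nrow(coords)))
  labels <- as.character(labels)
  if (length(labels) != nrow(coords))
    stopf("landmark set '%s': %d labels for %d landmarks", specimen,
          length(labels), nrow(coords))
  if (anyDuplicated(labels))
    stopf("landmark set '%s': duplicate label '%s'", specimen,
          labels[duplicated(labels)][1])
  dimnames(coords) <- NULL
  structure(list(labels = labels, coords = coords, frame = "RAS",
                 specimen = specimen),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set '%s': %d landmarks (RAS, mm)>\n",
              x$specimen, nrow(x$coords)))
  invisible(x)
}

#' @export
as.matrix.landmark_set <- function(x, ...) x$coords

check_comparable <- function(a, b) {
  if (nrow(a$coords) != nrow(b$coords))
    stopf("landmark sets not comparable: %d vs %d landmarks",
          nrow(a$coords), nrow(b$coords))
  mism <- which(a$labels != b$labels)
  if (length(mism))
    stopf("landmark label mismatch at position %d: '%s' vs '%s'",
          mism[1], a$labels[mism[1]], b$labels[mism[1]])
  invisible(TRUE)
}

#' Tidy a landmark set into a tibble
#'
#' @param x a [landmark_set()].
#' @param ... unused.
#' @return a tibble with columns specimen, label, x, y, z.
#' @export
tidy.landmark_set <- function(x, ...) {
  tibble::tibble(specimen = x$specimen, label = x$labels,
                 x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3])
}
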