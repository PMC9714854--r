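#' Read a landmark file
#'
#' Supports Slicer FCSV (`.fcsv`), Slicer markups JSON (`.json` /
#' `.mrk.json`) and plain CSV with header `label,x,y,z`. The file's declared
#' coordinate system is honored: LPS coordinates are converted to the
#' internal RAS frame (x and y negated). FCSV files without a
#' `# CoordinateSystem` header are taken as RAS.
#'
#' @param path file path.
#' @param specimen specimen identifier; defaults to the file stem.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path, specimen = NULL) {
  if (!file.exists(path)) stopf("landmark file does not exist: %s", path)
  specimen <- specimen %||% sub("\\.(fcsv|json|csv)$", "",
                                sub("\\.mrk\\.json$", "", basename(path)))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    fcsv = read_fcsv(path, specimen),
    json = read_markups_json(path, specimen),
    csv = read_landmarks_csv(path, specimen),
    stopf("unsupported landmark format '.%s' (expected fcsv/json/csv): %s",
          ext, path))
}

#' Write a landmark file
#'
#' Dialects: `"fcsv"` (Slicer fiducial CSV, written in RAS with an explicit
#' coordinate-system header), `"markups-json"` (Slicer markups, written in
#' LPS as Slicer does) and `"csv"` (`label,x,y,z` in RAS).
#'
#' @param lms a [landmark_set()].
#' @param path output path.
#' @param dialect one of `"fcsv"`, `"markups-json"`, `"csv"`; default guessed
#'   from the extension, falling back to fcsv.
#' @export
write_landmarks <- function(lms, path, dialect = NULL) {
  stopifnot(inherits(lms, "landmark_set"))
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, json = "markups-json", csv = "csv", "fcsv")
  }
  dialect <- match.arg(dialect, c("fcsv", "markups-json", "csv"))
  switch(dialect,
    fcsv = write_fcsv(lms, path),
    `markups-json` = write_markups_json(lms, path),
    csv = write_landmarks_csv(lms, path))
  invisible(path)
}

read_fcsv <- function(path, specimen) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  frame <- "RAS"
  cs <- regmatches(hdr, regexpr("CoordinateSystem\\s*=\\s*\\S+", hdr))
  if (length(cs)) {
    val <- toupper(sub(".*=\\s*", "", cs[1]))
    frame <- if (val %in% c("LPS", "1")) "LPS" else "RAS"
  }
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(data_idx)) stopf("FCSV contains no landmark rows: %s", path)
  tab <- utils::read.csv(text = lines[data_idx], header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stopf("FCSV has fewer than 4 columns: %s", path)
  coords <- suppressWarnings(cbind(as.numeric(tab[[2]]), as.numeric(tab[[3]]),
                                   as.numeric(tab[[4]])))
  bad <- which(!stats::complete.cases(coords) | !is.finite(rowSums(coords)))
  if (length(bad))
    stopf("FCSV '%s': missing or non-numeric coordinates at row %d",
          path, data_idx[bad[1]])
  labels <- if (ncol(tab) >= 12) as.character(tab[[12]]) else
    paste0("lm", seq_len(nrow(tab)))
  if (any(!nzchar(labels))) labels[!nzchar(labels)] <-
    paste0("lm", which(!nzchar(labels)))
  landmark_set(coords, labels, frame = frame, specimen = specimen)
}

write_fcsv <- function(lms, path) {
  n <- nrow(lms$coords)
  hdr <- c("# Markups fiducial file version = 4.11",
           "# CoordinateSystem = RAS",
           "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  rows <- vapply(seq_len(n), function(i) {
    sprintf("vtkMRMLMarkupsFiducialNode_%d,%s,%s,%s,0,0,0,1,1,1,0,%s,,",
            i,
            sprintf("%.10g", lms$coords[i, 1]),
            sprintf("%.10g", lms$coords[i, 2]),
            sprintf("%.10g", lms$coords[i, 3]),
            lms$labels[i])
  }, "")
  writeLines(c(hdr, rows), path)
}

read_markups_json <- function(path, specimen) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mk <- doc$markups[[1]]
  frame <- toupper(mk$coordinateSystem %||% "LPS")
  if (!frame %in% c("RAS", "LPS"))
    stopf("markups JSON '%s': unknown coordinate system '%s'", path, frame)
  cps <- mk$controlPoints
  if (!length(cps)) stopf("markups JSON contains no control points: %s", path)
  coords <- do.call(rbind, lapply(cps, function(cp) {
    pos <- unlist(cp$position)
    if (length(pos) != 3 || anyNA(suppressWarnings(as.numeric(pos))))
      stopf("markups JSON '%s': invalid position for point '%s'",
            path, cp$label %||% "?")
    as.numeric(pos)
  }))
  labels <- vapply(seq_along(cps), function(i)
    as.character(cps[[i]]$label %||% paste0("lm", i)), "")
  landmark_set(coords, labels, frame = frame, specimen = specimen)
}

write_markups_json <- function(lms, path) {
  # Slicer writes markups JSON in LPS; negate x,y on the way out
  coords <- lms$coords
  coords[, 1:2] <- -coords[, 1:2]
  cps <- lapply(seq_len(nrow(coords)), function(i) {
    list(id = as.character(i), label = lms$labels[i],
         position = coords[i, ],
         orientation = c(-1, 0, 0, 0, -1, 0, 0, 0, 1))
  })
  doc <- list(
    `@schema` = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json",
    markups = list(list(type = "Fiducial", coordinateSystem = "LPS",
                        controlPoints = cps)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(json, path)
}

read_landmarks_csv <- function(path, specimen) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stopf("landmark CSV '%s': header must contain label,x,y,z", path)
  coords <- cbind(as.numeric(tab$x), as.numeric(tab$y), as.numeric(tab$z))
  bad <- which(!is.finite(rowSums(coords)))
  if (length(bad))
    stopf("landmark CSV '%s': missing or non-numeric coordinates at row %d",
          path, bad[1] + 1L)
  landmark_set(coords, as.character(tab$label), specimen = specimen)
}

write_landmarks_csv <- function(lms, path) {
  lines <- c("label,x,y,z",
             vapply(seq_len(nrow(lms$coords)), function(i)
               paste(c(lms$labels[i], sprintf("%.10g", lms$coords[i, ])),
                     collapse = ","), ""))
  writeLines(lines, path)
}
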