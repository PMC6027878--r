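#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig dialect: blocks starting with `LM=<k>` followed by
#' `k` whitespace-separated coordinate pairs, with optional `IMAGE=`,
#' `ID=` and `SCALE=` keys (case-insensitive). Coordinates are multiplied
#' by `SCALE` (default 1.0) at read time, so returned units are mm
#' whenever SCALE is mm-per-pixel. Unknown keys are ignored with a
#' warning. Specimen metadata (stage/genotype/sex) is not representable
#' in TPS, so it is supplied separately and joined on specimen id.
#'
#' @param path TPS file path.
#' @param metadata data.frame with columns `id`, `stage`, `genotype`,
#'   `sex`, or a path to a CSV holding them. Every specimen id in the TPS
#'   file must be present.
#' @param flip_y negate y coordinates at read time (for sources whose
#'   pixel origin is top-left). Default `FALSE`: coordinates are used as
#'   stored, since Procrustes registration is invariant to rigid motion.
#' @param scheme a [wing_scheme()].
#' @return a [wing_set()].
#' @export
read_tps <- function(path, metadata, flip_y = FALSE, scheme = wing_scheme()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  p <- scheme$n_landmarks
  specs <- list()
  i <- 1L
  block <- 0L
  unknown <- character()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^([A-Za-z]+)=(.*)$", ln))[[1]]
    if (length(m) == 0 || toupper(m[2]) != "LM")
      stop("TPS parse error at line ", i, ": expected LM= block, got '",
           ln, "'")
    block <- block + 1L
    nlm <- suppressWarnings(as.integer(m[3]))
    if (is.na(nlm)) stop("TPS parse error at line ", i, ": bad LM= count")
    if (nlm != p)
      stop("block ", block, " (line ", i, "): LM=", nlm,
           " but scheme requires ", p, " landmarks")
    coords <- matrix(NA_real_, p, 2L)
    for (j in seq_len(p)) {
      i <- i + 1L
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("TPS parse error at line ", i,
             ": expected two numeric coordinates, got '", lines[i], "'")
      coords[j, ] <- xy
    }
    id <- NULL; img <- NULL; scale <- 1.0
    i <- i + 1L
    while (i <= length(lines) && nzchar(lines[i]) &&
           !grepl("^[Ll][Mm]=", lines[i])) {
      km <- regmatches(lines[i], regexec("^([A-Za-z]+)=(.*)$", lines[i]))[[1]]
      if (length(km) == 0)
        stop("TPS parse error at line ", i, ": '", lines[i], "'")
      key <- toupper(km[2]); val <- trimws(km[3])
      if (key == "ID") id <- val
      else if (key == "IMAGE") img <- val
      else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale) || scale <= 0)
          stop("TPS parse error at line ", i, ": bad SCALE '", val, "'")
      } else unknown <- c(unknown, key)
      i <- i + 1L
    }
    if (is.null(id)) id <- if (!is.null(img)) img else paste0("specimen", block)
    coords <- coords * scale
    if (flip_y) coords[, 2L] <- -coords[, 2L]
    specs[[length(specs) + 1L]] <- list(id = id, coords = coords)
  }
  if (length(unknown))
    warning("ignored unknown TPS key(s): ",
            paste(unique(unknown), collapse = ", "))
  if (!length(specs)) stop("no LM= blocks found in ", path)
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate specimen id(s) in TPS file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_metadata(metadata)
  metadata <- as.data.frame(metadata)
  metadata$id <- as.character(metadata$id)
  unmatched <- setdiff(ids, metadata$id)
  if (length(unmatched))
    stop("no metadata for specimen id(s): ",
         paste(unmatched, collapse = ", "))
  info <- metadata[match(ids, metadata$id), , drop = FALSE]
  rownames(info) <- NULL
  arr <- array(unlist(lapply(specs, `[[`, "coords")), c(p, 2L, length(specs)))
  wing_set(arr, info, scheme)
}

#' Write a wing_set to a TPS file
#'
#' Emits one `LM=` block per specimen with `ID=` and `SCALE=1.0` (the
#' stored coordinates are already in mm). Round-trips through
#' [read_tps()] to full double precision (text written with 15
#' significant digits).
#'
#' @param x a [wing_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path) {
  p <- dim(x$coords)[1]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(n_specimens(x))) {
    writeLines(paste0("LM=", p), con)
    writeLines(sprintf("%.15g %.15g", x$coords[, 1L, i], x$coords[, 2L, i]),
               con)
    writeLines(paste0("ID=", x$info$id[i]), con)
    writeLines("SCALE=1.0", con)
  }
  invisible(path)
}

#' Read a specimen metadata sidecar CSV
#'
#' @param path CSV with at least columns `id`, `stage`, `genotype`, `sex`.
#' @return data.frame, `id` as character.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "stage", "genotype", "sex")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop("metadata file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  md$id <- as.character(md$id)
  md
}

#' Write tabular pipeline output
#'
#' All pipeline products are written as UTF-8 CSV with a header row,
#' '.' decimal separator and empty cells for missing values.
#'
#' @param records data.frame (possibly 0-row: a header-only file is
#'   written).
#' @param path output file.
#' @param comment optional character vector written as leading `#` lines
#'   (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, comment = NULL) {
  records <- as.data.frame(records)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(records, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read tabular pipeline output written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
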