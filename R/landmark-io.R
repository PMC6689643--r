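#' Read landmark configurations
#'
#' Reads specimen landmark coordinates from a long CSV
#' (`specimen_id, landmark, x, y, z`), a wide CSV (`specimen_id` plus
#' `<name>_x, <name>_y, <name>_z` columns), or a minimal TPS file
#' (`LM3=`/`LM=` blocks with `ID=` keys; `SCALE=` lines are ignored and
#' units are taken as given). Landmarks are remapped from file order to
#' scheme order; every landmark of the scheme must be present for every
#' specimen.
#'
#' @param path file path.
#' @param scheme a [landmark_scheme()].
#' @param format `"auto"` (by extension), `"csv-long"`, `"csv-wide"` or
#'   `"tps"`.
#' @return A `landmark_set`: list with `coords` (k x d x n array, dimnames
#'   landmark/axis/specimen), `ids`, and `scheme`.
#' @export
read_landmarks <- function(path, scheme,
                           format = c("auto", "csv-long", "csv-wide", "tps")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  if (format == "tps") return(read_landmarks_tps(path, scheme))
  head1 <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (format == "csv-long" ||
      (format == "csv" && all(c("landmark", "x") %in% head1)))
    read_landmarks_long(path, scheme)
  else
    read_landmarks_wide(path, scheme)
}

axis_letters <- function(d) c("x", "y", "z")[seq_len(d)]

# full-precision CSV so that read(write(x)) round-trips bit-exactly
write_csv_exact <- function(df, path) {
  for (cl in names(df)) if (is.double(df[[cl]])) {
    v <- sprintf("%.17g", df[[cl]])
    v[is.na(df[[cl]])] <- ""
    df[[cl]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

new_landmark_set <- function(coords, ids, scheme) {
  dimnames(coords) <- list(scheme$names, axis_letters(scheme$dimension), ids)
  structure(list(coords = coords, ids = ids, scheme = scheme),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark set: %d specimens, %d landmarks, %dD\n",
              length(x$ids), x$scheme$k, x$scheme$dimension))
  invisible(x)
}

check_complete <- function(tab, scheme, id) {
  missing <- setdiff(scheme$names, tab$landmark)
  if (length(missing))
    stop(sprintf("specimen '%s' is missing landmark(s): %s", id,
                 paste(missing, collapse = ", ")))
  extra <- setdiff(tab$landmark, scheme$names)
  if (length(extra))
    stop(sprintf("specimen '%s' has unknown landmark(s): %s", id,
                 paste(extra, collapse = ", ")))
  if (anyDuplicated(tab$landmark))
    stop(sprintf("specimen '%s' has duplicated landmarks", id))
}

read_landmarks_long <- function(path, scheme) {
  d <- scheme$dimension
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "landmark", axis_letters(d))
  if (!all(need %in% names(df)))
    stop("long landmark CSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$specimen_id)
  coords <- array(NA_real_, c(scheme$k, d, length(ids)))
  for (i in seq_along(ids)) {
    tab <- df[df$specimen_id == ids[i], , drop = FALSE]
    check_complete(tab, scheme, ids[i])
    m <- as.matrix(tab[match(scheme$names, tab$landmark), axis_letters(d)])
    if (anyNA(m) || any(!is.finite(m)))
      stop(sprintf("specimen '%s' has missing or non-finite coordinates",
                   ids[i]))
    coords[, , i] <- m
  }
  new_landmark_set(coords, ids, scheme)
}

read_landmarks_wide <- function(path, scheme) {
  d <- scheme$dimension
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"specimen_id" %in% names(df))
    stop("wide landmark CSV must have a specimen_id column")
  if (anyDuplicated(df$specimen_id)) stop("duplicate specimen id in file")
  cols <- as.vector(t(outer(scheme$names, axis_letters(d), paste, sep = "_")))
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("wide landmark CSV is missing column(s): ",
         paste(utils::head(missing, 6), collapse = ", "))
  m <- as.matrix(df[, cols])
  if (anyNA(m) || any(!is.finite(m)))
    stop("missing or non-finite coordinates in ",
         paste(df$specimen_id[!stats::complete.cases(m)], collapse = ", "))
  coords <- array(t(m), c(d, scheme$k, nrow(df)))
  coords <- aperm(coords, c(2, 1, 3))
  new_landmark_set(coords, df$specimen_id, scheme)
}

read_landmarks_tps <- function(path, scheme) {
  d <- scheme$dimension
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines)
  if (!length(starts)) stop("no LM/LM3 records found in TPS file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- character(0); mats <- list()
  for (b in seq_along(starts)) {
    blk <- lines[starts[b]:ends[b]]
    k <- as.integer(sub("^LM3?=", "", blk[1]))
    if (k != scheme$k)
      stop(sprintf("TPS block %d has %d landmarks; scheme expects %d",
                   b, k, scheme$k))
    coord_lines <- blk[2:(k + 1)]
    m <- do.call(rbind, lapply(strsplit(coord_lines, "[ \t]+"), as.numeric))
    if (ncol(m) != d)
      stop(sprintf("TPS block %d has dimension %d; scheme expects %d",
                   b, ncol(m), d))
    idl <- grep("^ID=", blk, value = TRUE)
    ids[b] <- if (length(idl)) sub("^ID=", "", idl[1]) else sprintf("tps_%d", b)
    if (anyNA(m)) stop("missing coordinate in TPS block for ", ids[b])
    mats[[b]] <- m
  }
  if (anyDuplicated(ids)) stop("duplicate specimen id in TPS file")
  coords <- array(unlist(mats), c(scheme$k, d, length(ids)))
  new_landmark_set(coords, ids, scheme)
}

#' Write landmark configurations
#'
#' @param x a `landmark_set` (or a single k x d matrix with `ids`/`scheme`
#'   supplied via attributes of the set).
#' @param path output file.
#' @param format `"csv-long"`, `"csv-wide"` or `"tps"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path, format = c("csv-long", "csv-wide", "tps")) {
  format <- match.arg(format)
  sc <- x$scheme; d <- sc$dimension; n <- length(x$ids)
  if (format == "csv-long") {
    df <- data.frame(
      specimen_id = rep(x$ids, each = sc$k),
      landmark = rep(sc$names, n))
    flat <- matrix(aperm(x$coords, c(1, 3, 2)), ncol = d)
    for (j in seq_len(d)) df[[axis_letters(d)[j]]] <- flat[, j]
    write_csv_exact(df, path)
  } else if (format == "csv-wide") {
    m <- t(apply(x$coords, 3, function(cf) as.vector(t(cf))))
    colnames(m) <- as.vector(t(outer(sc$names, axis_letters(d),
                                     paste, sep = "_")))
    df <- data.frame(specimen_id = x$ids, m, check.names = FALSE)
    write_csv_exact(df, path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(n)) {
      writeLines(sprintf("LM3=%d", sc$k), con)
      m <- x$coords[, , i]
      writeLines(apply(m, 1, function(r)
        paste(sprintf("%.17g", r), collapse = " ")), con)
      writeLines(sprintf("ID=%s", x$ids[i]), con)
    }
  }
  invisible(path)
}

metadata_required <- c("specimen_id", "sex", "age_class", "captivity",
                       "population", "latitude", "longitude",
                       "temperature", "precipitation")
metadata_optional <- c("island", "age_years", "generation")

#' Read a specimen metadata table
#'
#' Required columns: `specimen_id`, `sex` (0 female / 1 male), `age_class`
#' (0 young adult / 1 adult), `captivity` (0 wild / 1 founder /
#' 2 captive-born), `population`, `latitude`, `longitude`, `temperature`
#' (annual mean, degrees C), `precipitation` (annual total, mm). Optional:
#' `island` (0/1), `age_years`, `generation`. Optional columns that are
#' absent stay absent (no zero-filling); missing values inside optional
#' columns are kept as `NA`.
#'
#' @param path CSV file path.
#' @return A `data.frame` of validated specimen metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param df a metadata data.frame to validate in place.
#' @export
validate_metadata <- function(df) {
  missing <- setdiff(metadata_required, names(df))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$specimen_id))
    stop("duplicate specimen_id in metadata: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]),
               collapse = ", "))
  check_codes <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad))
      stop(sprintf("invalid %s value '%s' in metadata row %d", col,
                   df[[col]][bad[1]], bad[1]))
  }
  check_codes("sex", 0:1)
  check_codes("age_class", 0:1)
  check_codes("captivity", 0:2)
  if ("island" %in% names(df)) {
    bad <- which(!(is.na(df$island) | df$island %in% 0:1))
    if (length(bad))
      stop(sprintf("invalid island value in metadata row %d", bad[1]))
  }
  if (any(!nzchar(as.character(df$population))))
    stop("empty population label in metadata")
  df
}

#' @rdname read_metadata
#' @export
write_metadata <- function(df, path) {
  write_csv_exact(df, path)
  invisible(path)
}

#' Join landmark configurations with specimen metadata
#'
#' Inner join on `specimen_id`; unmatched ids on either side are reported,
#' not silently dropped.
#'
#' @param landmarks a `landmark_set`.
#' @param metadata a validated metadata data.frame.
#' @return A `morph_dataset`: list with `landmarks` (subset, metadata order),
#'   `metadata` (subset), and `unmatched` (list of ids present on one side
#'   only).
#' @export
join_dataset <- function(landmarks, metadata) {
  common <- intersect(landmarks$ids, metadata$specimen_id)
  if (!length(common))
    stop("no specimen ids shared between landmarks and metadata")
  unmatched <- list(
    landmarks_only = setdiff(landmarks$ids, common),
    metadata_only = setdiff(metadata$specimen_id, common))
  meta <- metadata[match(common, metadata$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  lm <- new_landmark_set(
    landmarks$coords[, , match(common, landmarks$ids), drop = FALSE],
    common, landmarks$scheme)
  structure(list(landmarks = lm, metadata = meta, unmatched = unmatched),
            class = "morph_dataset")
}

#' @export
print.morph_dataset <- function(x, ...) {
  cat(sprintf("morph dataset: %d specimens, %d populations (%d unmatched ids dropped)\n",
              nrow(x$metadata), length(unique(x$metadata$population)),
              length(x$unmatched$landmarks_only) +
                length(x$unmatched$metadata_only)))
  invisible(x)
}
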