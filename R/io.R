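# Readers and writers for the pipeline's plain-text interchange formats:
# kinetic CSV, PIE TSV (wide and long), multi-frame XYZ, result JSON.

#' Write / read a kinetic dataset as CSV
#'
#' Columns: `substrate_uM`, `rate_nmol_min_mg`, `replicate`, `condition`.
#' Values round-trip at full double precision.
#'
#' @param data A kinetic dataset data frame.
#' @param path Output file.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_kinetic_csv <- function(data, path) {
  validate_kinetic_dataset(data)
  out <- data
  for (col in c("substrate_uM", "rate_nmol_min_mg")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  # quote only the free-text columns; quoted numerics defeat colClasses
  quote_cols <- which(!vapply(data, is.numeric, logical(1)))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = unname(quote_cols), qmethod = "double")
  invisible(path)
}

#' @rdname write_kinetic_csv
#' @export
read_kinetic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(substrate_uM = "numeric",
                                       rate_nmol_min_mg = "numeric"))
  validate_kinetic_dataset(df)
  df
}

#' Write / read a PIE matrix as TSV
#'
#' The wide format has one row per conformation (first column
#' `conformation_id`, remaining columns one per fragment label). The reader
#' also accepts the long format with columns `conformation_id`,
#' `fragment_label`, `pie_kj_mol`, which it pivots to the same matrix.
#'
#' @param m A [pie_matrix()].
#' @param path File path.
#' @return `path` (write) or a `pie_matrix` (read).
#' @export
write_pie_tsv <- function(m, path) {
  stopifnot(inherits(m, "pie_matrix"))
  df <- data.frame(conformation_id = rownames(m),
                   matrix(sprintf("%.17g", unclass(m)), nrow(m), ncol(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- colnames(m)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pie_tsv
#' @export
read_pie_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  long_cols <- c("conformation_id", "fragment_label", "pie_kj_mol")
  if (all(long_cols %in% names(df))) {
    ids <- unique(df$conformation_id)
    frags <- unique(df$fragment_label)
    values <- matrix(NA_real_, length(ids), length(frags),
                     dimnames = list(ids, frags))
    values[cbind(match(df$conformation_id, ids),
                 match(df$fragment_label, frags))] <- df$pie_kj_mol
    if (any(is.na(values))) {
      stop("long-format PIE table has missing conformation x fragment cells",
           call. = FALSE)
    }
    return(pie_matrix(values, ids, frags))
  }
  if (names(df)[1] != "conformation_id") {
    stop("PIE TSV must start with a conformation_id column (wide) or carry long-format columns",
         call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  pie_matrix(values, df$conformation_id, names(df)[-1])
}

#' Write / read a multi-frame XYZ trajectory
#'
#' Standard XYZ convention: per frame an atom-count line, a comment line
#' (`frame <i>`), then one `element x y z` line per atom, coordinates in
#' Angstrom. All frames must have the same atom count and element order.
#'
#' @param traj A `trajectory` object.
#' @param path File path.
#' @return `path` (write) or a `trajectory` (read).
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n_atoms <- length(traj$atom_names)
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(as.character(n_atoms), con)
    writeLines(sprintf("frame %d", i), con)
    writeLines(sprintf("%s %.17g %.17g %.17g",
                       traj$atom_names, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  atom_names <- NULL
  pos <- 1L
  frame_no <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) {
      pos <- pos + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    frame_no <- frame_no + 1L
    if (is.na(n) || n < 1) {
      stop(sprintf("XYZ frame %d (line %d): invalid atom count '%s'",
                   frame_no, pos, lines[pos]), call. = FALSE)
    }
    if (pos + 1L + n > length(lines)) {
      stop(sprintf("XYZ frame %d (line %d): truncated frame", frame_no, pos),
           call. = FALSE)
    }
    body <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad)) {
      stop(sprintf("XYZ frame %d (line %d): malformed atom line", frame_no,
                   pos + 1L + bad[1]), call. = FALSE)
    }
    names_i <- vapply(parts, `[[`, character(1), 1L)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(coords))) {
      stop(sprintf("XYZ frame %d (line %d): non-numeric coordinates",
                   frame_no, pos), call. = FALSE)
    }
    if (is.null(atom_names)) {
      atom_names <- names_i
    } else if (length(names_i) != length(atom_names) ||
               !all(names_i == atom_names)) {
      stop(sprintf("XYZ frame %d (line %d): atom count or order differs from frame 1",
                   frame_no, pos), call. = FALSE)
    }
    rownames(coords) <- names_i
    colnames(coords) <- c("x", "y", "z")
    frames[[frame_no]] <- coords
    pos <- pos + 2L + n
  }
  structure(list(frames = frames, atom_names = atom_names, truth = NULL),
            class = "trajectory")
}

#' Wrap a stage result in a reproducibility envelope
#'
#' Envelopes record the stage name, package version, parameters, an MD5
#' digest of every input file, and the results payload; written as JSON with
#' fixed field order and full numeric precision so reruns diff cleanly.
#'
#' @param stage Stage name.
#' @param parameters Named list of stage parameters (include the seed).
#' @param payload Results payload (list / data frame).
#' @param input_paths Character vector of input files to digest (optional).
#' @return A list of class `result_envelope`.
#' @export
result_envelope <- function(stage, parameters, payload, input_paths = character()) {
  digests <- if (length(input_paths)) {
    d <- tools::md5sum(input_paths)
    stats::setNames(as.character(d), basename(input_paths))
  } else {
    NULL
  }
  structure(list(stage = stage,
                 package_version = as.character(utils::packageVersion("rssmet")),
                 input_digests = digests,
                 parameters = parameters,
                 payload = payload,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "result_envelope")
}

#' Write a result envelope (or any list) as JSON
#'
#' @param x Object to serialize.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, "result_envelope")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
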