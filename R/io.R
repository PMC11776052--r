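gro_role_map <- c(H = "head", T = "tail", TT = "terminal_tail", W = "water")
gro_name_map <- setNames(names(gro_role_map), gro_role_map)

#' Write configurations to a GRO file
#'
#' Standard GROMACS GRO layout (nm, three-decimal coordinates, box line
#' footer); roles are encoded in atom names (H, T, TT, W) with residue
#' names LIP/SOL and the residue index carrying the lipid id. Multiple
#' frames are concatenated.
#'
#' @param config A [particle_configuration()] or a list of them.
#' @param path Output file path.
#' @param times Optional per-frame times (ps) written into the title line.
#' @return Invisibly, `path`.
#' @export
write_gro <- function(config, path, times = NULL) {
  frames <- if (inherits(config, "particle_configuration")) list(config) else config
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    n <- n_particles(fr)
    t <- if (is.null(times)) (fi - 1) else times[fi]
    writeLines(sprintf("porecv configuration t= %.3f", t), con)
    writeLines(sprintf("%5d", n), con)
    resid <- ifelse(is.na(fr$lipid_ids),
                    cumsum(is.na(fr$lipid_ids)) + max(0L, fr$lipid_ids, na.rm = TRUE),
                    fr$lipid_ids)
    resname <- ifelse(fr$roles == "water", "SOL", "LIP")
    atnm <- gro_name_map[fr$roles]
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid %% 100000L, resname, atnm,
                     seq_len(n) %% 100000L,
                     fr$positions[, 1], fr$positions[, 2], fr$positions[, 3])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}

#' Read configurations from a GRO file
#'
#' @param path GRO file (possibly multi-frame).
#' @return A [particle_configuration()] for a single frame, else a list of
#'   them. Coordinates are in nm (GRO native); roles are inferred from atom
#'   names via the map H/T/TT/W.
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    if (i + 1L > length(lines)) stop("truncated GRO file at line ", i)
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed atom-count line at line ", i + 1L)
    if (i + 1L + n + 1L > length(lines))
      stop("GRO frame starting at line ", i, " is truncated (missing box line)")
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    pos <- matrix(NA_real_, n, 3)
    roles <- character(n)
    lip <- integer(n)
    for (k in seq_len(n)) {
      ln <- atom_lines[k]
      if (nchar(ln) < 44L)
        stop("malformed GRO atom line at line ", i + 1L + k, ": too short")
      resid <- suppressWarnings(as.integer(substr(ln, 1, 5)))
      atnm <- trimws(substr(ln, 11, 15))
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                           substr(ln, 29, 36),
                                           substr(ln, 37, 44))))
      if (any(is.na(xyz)) || is.na(resid))
        stop("malformed GRO atom line at line ", i + 1L + k)
      if (!atnm %in% names(gro_role_map))
        stop("unknown atom name '", atnm, "' at line ", i + 1L + k,
             "; known names: ", paste(names(gro_role_map), collapse = ", "))
      pos[k, ] <- xyz
      roles[k] <- gro_role_map[[atnm]]
      lip[k] <- resid
    }
    box <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1L + n + 1L]),
                                                "\\s+")[[1]]))
    if (length(box) < 3L || any(is.na(box[1:3])))
      stop("missing or malformed box line at line ", i + 1L + n + 1L)
    lip[roles == "water"] <- NA_integer_
    frames[[length(frames) + 1L]] <-
      particle_configuration(pos, roles, lip, box[1:3])
    i <- i + n + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in ", path)
  if (length(frames) == 1L) frames[[1L]] else frames
}

#' Write configurations to an XYZ file
#'
#' Extended XYZ with the box and unit declared on the comment line
#' (`box Lx Ly Lz units nm`); atom names encode roles (H, T, TT, W).
#'
#' @inheritParams write_gro
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(config, path, times = NULL) {
  frames <- if (inherits(config, "particle_configuration")) list(config) else config
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    t <- if (is.null(times)) (fi - 1) else times[fi]
    writeLines(sprintf("%d", n_particles(fr)), con)
    writeLines(sprintf("box %.6f %.6f %.6f units nm t= %.3f",
                       fr$box[1], fr$box[2], fr$box[3], t), con)
    writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", gro_name_map[fr$roles],
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Read configurations from an XYZ file
#'
#' The comment line must declare the box and units
#' (`box Lx Ly Lz units nm|angstrom`); angstrom coordinates are converted
#' to nm. Lipid ids are reconstructed by grouping consecutive H/T/TT runs.
#'
#' @param path XYZ file (possibly multi-frame).
#' @return A [particle_configuration()] or list of them.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ count line at line ", i)
    if (i + 1L + n > length(lines))
      stop("XYZ frame at line ", i, " declares ", n,
           " atoms but the file ends early")
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexec("box\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)",
                            comment))[[1]]
    if (length(m) != 4L)
      stop("XYZ comment line ", i + 1L, " lacks a 'box Lx Ly Lz' declaration")
    box <- as.numeric(m[2:4])
    scale <- 1
    um <- regmatches(comment, regexec("units\\s+(\\w+)", comment))[[1]]
    if (length(um) == 2L) {
      if (tolower(um[2]) %in% c("angstrom", "a"))
        scale <- 0.1
      else if (tolower(um[2]) != "nm")
        stop("unknown XYZ unit declaration: ", um[2])
    }
    toks <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad))
      stop("malformed XYZ atom line at line ", i + 1L + bad[1])
    nm <- vapply(toks, `[[`, character(1), 1L)
    if (!all(nm %in% names(gro_role_map)))
      stop("unknown atom name(s): ",
           paste(unique(nm[!nm %in% names(gro_role_map)]), collapse = ", "),
           "; known names: ", paste(names(gro_role_map), collapse = ", "))
    pos <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))) * scale
    roles <- unname(gro_role_map[nm])
    lip <- rep(NA_integer_, n)
    lid <- 0L
    for (k in seq_len(n)) {
      if (roles[k] == "water") next
      if (roles[k] == "head") lid <- lid + 1L
      lip[k] <- lid
    }
    frames[[length(frames) + 1L]] <-
      particle_configuration(pos, roles, lip, box * scale)
    i <- i + n + 2L
  }
  if (!length(frames)) stop("no frames found in ", path)
  if (length(frames) == 1L) frames[[1L]] else frames
}

#' Read coordinates in GRO or XYZ format
#'
#' @param path Coordinate file.
#' @param format `"gro"`, `"xyz"`, or `"auto"` (by file extension).
#' @return A [particle_configuration()] or list of frames.
#' @export
read_coordinates <- function(path, format = c("auto", "gro", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gro", "xyz")) ext
              else stop("cannot infer format from extension '", ext, "'")
  }
  if (format == "gro") read_gro(path) else read_xyz(path)
}

#' Write a COLVAR-style time series
#'
#' Whitespace-separated numeric columns preceded by a `#! FIELDS` header
#' naming them, as consumed by common biased-MD toolchains.
#'
#' @param df Data frame of numeric columns (first usually `time`).
#' @param path Output path.
#' @param digits Significant digits (default 10).
#' @return Invisibly, `path`.
#' @export
write_series <- function(df, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  fmt <- paste0("%.", digits, "g")
  rows <- do.call(paste, c(lapply(df, function(col) sprintf(fmt, col)),
                           sep = " "))
  writeLines(rows, con)
  invisible(path)
}

#' Read a COLVAR-style time series
#'
#' @param path File with a `#! FIELDS name...` header followed by numeric
#'   rows; other `#` comment lines are skipped.
#' @return Data frame with the named columns.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#!\\s*FIELDS", lines)
  if (!length(hdr))
    stop("no '#! FIELDS' header found in ", path)
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", lines[hdr[1]])),
                     "\\s+")[[1]]
  body <- lines[-seq_len(hdr[1])]
  body <- body[!grepl("^\\s*#", body) & nzchar(trimws(body))]
  if (!length(body)) {
    df <- as.data.frame(matrix(numeric(0), ncol = length(fields)))
    names(df) <- fields
    return(df)
  }
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) != length(fields)))
    stop("ragged data row in ", path, " (expected ", length(fields),
         " columns)")
  flat <- unlist(toks)
  vals <- suppressWarnings(as.numeric(flat))
  bad <- is.na(vals) & !tolower(flat) %in% c("nan", "na", "inf", "-inf")
  if (any(bad)) stop("non-numeric data in ", path)
  m <- matrix(vals, ncol = length(fields), byrow = TRUE)
  df <- as.data.frame(m)
  names(df) <- fields
  df
}

#' Extract a named column from a series
#'
#' @param df Data frame from [read_series()].
#' @param name Column name.
#' @return Numeric vector; errors naming the available columns when absent.
#' @export
series_column <- function(df, name) {
  if (!name %in% names(df))
    stop("no column '", name, "'; available: ",
         paste(names(df), collapse = ", "))
  df[[name]]
}

#' Write a free-energy profile as 3-column text
#'
#' Columns `cv`, `G` (kJ/mol) and `err`; unsampled bins carry `nan`.
#'
#' @param profile A [free_energy_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(cv = profile$grid,
                   G = ifelse(is.na(profile$G), NaN, profile$G),
                   err = ifelse(is.na(profile$err), NaN, profile$err))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS cv G err", con)
  writeLines(sprintf("%.10g %.10g %.10g", df$cv, df$G, df$err), con)
  invisible(path)
}

#' Read a 3-column free-energy profile
#'
#' @param path File from [write_profile()] (or any `cv G [err]` text).
#' @return A [free_energy_profile()].
#' @export
read_profile <- function(path) {
  df <- read_series(path)
  if (!all(c("cv", "G") %in% names(df)))
    stop("profile file must carry 'cv' and 'G' columns")
  err <- if ("err" %in% names(df)) df$err else rep(NA_real_, nrow(df))
  free_energy_profile(df$cv, df$G, err = err)
}
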