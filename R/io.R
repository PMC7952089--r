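# text-format trajectory and configuration IO
#
# Two interchange formats are supported, both plain text:
#  * LAMMPS dump: per frame "ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS /
#    ATOMS id mol type x y z".  Types are 1 = A, 2 = B; mol is the polymer id.
#  * XYZ: count line, comment line carrying `time=... box=Lx Ly Lz`, then
#    "El x y z mol" rows (the mol column is an extension; absent mol ids are
#    reconstructed as one polymer per bead).

#' Write a trajectory to disk
#'
#' @param traj a `trajectory` or single [configuration()].
#' @param path output file.
#' @param format `"lammps_dump"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("lammps_dump", "xyz")) {
  format <- match.arg(format)
  frames <- if (inherits(traj, "trajectory")) traj$frames else list(traj)
  times <- if (inherits(traj, "trajectory")) traj$times else 0
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    n <- nrow(fr$positions)
    if (format == "lammps_dump") {
      writeLines(c("ITEM: TIMESTEP", format(times[f], digits = 12),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   "ITEM: BOX BOUNDS pp pp pp",
                   sprintf("0 %.10g", fr$box[1]),
                   sprintf("0 %.10g", fr$box[2]),
                   sprintf("0 %.10g", fr$box[3]),
                   "ITEM: ATOMS id mol type x y z"), con)
      if (n > 0)
        writeLines(sprintf("%d %d %d %.9g %.9g %.9g", seq_len(n),
                           fr$polymer, ifelse(fr$species == "A", 1L, 2L),
                           fr$positions[, 1], fr$positions[, 2],
                           fr$positions[, 3]), con)
    } else {
      writeLines(c(as.character(n),
                   sprintf("time=%.10g box=%.10g %.10g %.10g", times[f],
                           fr$box[1], fr$box[2], fr$box[3])), con)
      if (n > 0)
        writeLines(sprintf("%s %.9g %.9g %.9g %d", fr$species,
                           fr$positions[, 1], fr$positions[, 2],
                           fr$positions[, 3], fr$polymer), con)
    }
  }
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Atoms are re-sorted by id; coordinates may use scientific notation; a
#' malformed or truncated frame raises an error naming the offending line or
#' the last complete frame.
#'
#' @param path input file.
#' @param format `"lammps_dump"` or `"xyz"`.
#' @param spec optional [simulation_spec()] attached to the configurations.
#' @return a `trajectory` (with zero energies; only geometry is stored).
#' @export
read_trajectory <- function(path, format = c("lammps_dump", "xyz"),
                            spec = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list(); times <- numeric(0)
  i <- 1L; n_complete <- 0L
  bad <- function(what, ln) {
    stop(sprintf("%s at line %d (last complete frame: %d)", what, ln,
                 n_complete), call. = FALSE)
  }
  if (format == "lammps_dump") {
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      if (!startsWith(lines[i], "ITEM: TIMESTEP")) bad("expected ITEM: TIMESTEP", i)
      if (i + 8 > length(lines)) bad("truncated header", i)
      tm <- suppressWarnings(as.numeric(lines[i + 1]))
      if (is.na(tm)) bad("unreadable timestep", i + 1L)
      if (!startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS"))
        bad("expected ITEM: NUMBER OF ATOMS", i + 2L)
      n <- suppressWarnings(as.integer(lines[i + 3]))
      if (is.na(n) || n < 0) bad("unreadable atom count", i + 3L)
      if (!startsWith(lines[i + 4], "ITEM: BOX BOUNDS"))
        bad("expected ITEM: BOX BOUNDS", i + 4L)
      box <- numeric(3)
      for (d in 1:3) {
        b <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 4 + d]),
                                                  "\\s+")[[1]]))
        if (length(b) < 2 || anyNA(b[1:2])) bad("unreadable box bounds", i + 4L + d)
        box[d] <- b[2] - b[1]
      }
      hdr <- lines[i + 8]
      if (!startsWith(hdr, "ITEM: ATOMS")) bad("expected ITEM: ATOMS", i + 8L)
      cols <- strsplit(trimws(sub("ITEM: ATOMS", "", hdr)), "\\s+")[[1]]
      need <- c("id", "type", "x", "y", "z")
      if (!all(need %in% cols)) bad("dump misses required columns", i + 8L)
      if (i + 8 + n > length(lines)) bad("truncated frame body", length(lines))
      rows <- lines[i + 8 + seq_len(n)]
      m <- matrix(NA_real_, n, length(cols))
      for (k in seq_len(n)) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(rows[k]), "\\s+")[[1]]))
        if (length(v) != length(cols) || anyNA(v)) bad("malformed atom row", i + 8L + k)
        m[k, ] <- v
      }
      colnames(m) <- cols
      ord <- order(m[, "id"])
      m <- m[ord, , drop = FALSE]
      mol <- if ("mol" %in% cols) as.integer(m[, "mol"]) else seq_len(n)
      frames[[length(frames) + 1L]] <-
        configuration(m[, c("x", "y", "z"), drop = FALSE],
                      ifelse(m[, "type"] == 1, "A", "B"), mol,
                      ave_index(mol), box, spec)
      times <- c(times, tm)
      n_complete <- n_complete + 1L
      i <- i + 9L + n
    }
  } else {
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      n <- suppressWarnings(as.integer(lines[i]))
      if (is.na(n) || n < 0) bad("unreadable atom count", i)
      if (i + 1 + n > length(lines)) bad("truncated frame body", length(lines))
      cm <- lines[i + 1]
      tm <- .field_num(cm, "time", 0)
      box <- .field_vec3(cm, "box")
      if (anyNA(box)) bad("comment line misses box=Lx Ly Lz", i + 1L)
      rows <- lines[i + 1 + seq_len(n)]
      sp <- character(n); pos <- matrix(NA_real_, n, 3); mol <- integer(n)
      for (k in seq_len(n)) {
        v <- strsplit(trimws(rows[k]), "\\s+")[[1]]
        if (length(v) < 4) bad("malformed atom row", i + 1L + k)
        sp[k] <- v[1]
        pos[k, ] <- suppressWarnings(as.numeric(v[2:4]))
        if (anyNA(pos[k, ])) bad("malformed coordinates", i + 1L + k)
        mol[k] <- if (length(v) >= 5) as.integer(v[5]) else k
      }
      frames[[length(frames) + 1L]] <-
        configuration(pos, sp, mol, ave_index(mol), box, spec)
      times <- c(times, tm)
      n_complete <- n_complete + 1L
      i <- i + 2L + n
    }
  }
  structure(list(times = times, frames = frames,
                 epot = rep(NA_real_, length(frames)),
                 ekin = rep(NA_real_, length(frames)),
                 stride = NA_integer_, spec = spec, seed = NA_integer_,
                 friction = NA_real_, timestep = NA_real_),
            class = "trajectory")
}

# per-polymer running index (beads assumed listed in chain order within id)
ave_index <- function(mol) {
  idx <- integer(length(mol))
  for (m in unique(mol)) idx[mol == m] <- seq_len(sum(mol == m))
  idx
}

.field_num <- function(line, key, default = NA_real_) {
  m <- regmatches(line, regexec(paste0(key, "=([-0-9.eE+]+)"), line))[[1]]
  if (length(m) < 2) default else as.numeric(m[2])
}
.field_vec3 <- function(line, key) {
  m <- regmatches(line, regexec(
    paste0(key, "=([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)"),
    line))[[1]]
  if (length(m) < 4) rep(NA_real_, 3) else as.numeric(m[2:4])
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key value`), `#` comments.  The file
#' is interpreted as a [simulation_spec()] when it contains `valence_A`, or
#' as [theory_params()] when it contains `L1`.  Unknown or duplicate keys
#' are errors; missing required keys are reported by name.
#'
#' @param path file path.
#' @return a `simulation_spec` or `theory_params`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s*=\\s*|\\s+")[[1]]
    if (length(parts) < 2) stop("unparseable config line: ", ln)
    key <- parts[1]
    val <- paste(parts[-1], collapse = " ")
    if (key %in% names(kv)) stop("duplicate key in config: ", key)
    kv[[key]] <- val
  }
  num <- function(x) as.numeric(strsplit(x, "\\s+")[[1]])
  if ("L1" %in% names(kv)) {
    allowed <- c("L1", "L2", "Kd", "Kb", "vb_ns", "wb_ns")
    unknown <- setdiff(names(kv), allowed)
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    req <- c("L1", "L2")
    miss <- setdiff(req, names(kv))
    if (length(miss)) stop("missing required keys: ",
                           paste(miss, collapse = ", "))
    args <- lapply(kv, num)
    do.call(theory_params, args)
  } else {
    allowed <- c("valence_A", "valence_B", "count_A", "count_B", "box", "U0",
                 "sticker_diameter", "mean_linker_length", "bond_stiffness",
                 "E_rep", "friction", "timestep", "temperature", "seed",
                 "init_mode")
    unknown <- setdiff(names(kv), allowed)
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    req <- c("valence_A", "valence_B", "count_A", "count_B", "box", "U0")
    miss <- setdiff(req, names(kv))
    if (length(miss)) stop("missing required keys: ",
                           paste(miss, collapse = ", "))
    args <- kv
    for (k in setdiff(names(args), "init_mode")) args[[k]] <- num(args[[k]])
    do.call(simulation_spec, args)
  }
}

#' Write a configuration file for a spec or parameter set
#'
#' @param x a `simulation_spec` or `theory_params`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(x, path) {
  if (inherits(x, "theory_params")) {
    keys <- c("L1", "L2", "Kd", "Kb", "vb_ns", "wb_ns")
    vals <- vapply(keys, function(k) paste(format(x[[k]], digits = 15),
                                           collapse = " "), "")
  } else if (inherits(x, "simulation_spec")) {
    keys <- c("valence_A", "valence_B", "count_A", "count_B", "box", "U0",
              "sticker_diameter", "mean_linker_length", "bond_stiffness",
              "E_rep", "friction", "timestep", "temperature", "seed",
              "init_mode")
    vals <- vapply(keys, function(k) paste(format(x[[k]], digits = 15),
                                           collapse = " "), "")
  } else stop("unsupported object")
  writeLines(paste(keys, "=", vals), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, full parameter set, seeds, package version,
#' timestamp, and md5 digests of input/output files, as JSON next to the
#' outputs.  Deterministic stages can be re-run bit-identically from the
#' manifest alone.
#'
#' @param path manifest path (.json).
#' @param command command name.
#' @param params named list of parameters.
#' @param seed integer seed(s).
#' @param files character vector of associated files to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params, seed = NA_integer_,
                           files = character(0)) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    params = params,
    seed = seed,
    package = "magicratio",
    version = as.character(utils::packageVersion("magicratio")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    digests = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
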