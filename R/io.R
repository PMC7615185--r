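# Readers and writers for the package's plain-text interchange formats:
# schema-checked CSV tables, I-V recordings with JSON sidecars,
# transient-absorption cubes, photocycle scheme JSON, PDB topologies and
# XYZ coordinate frames, manifests and run configs.

#' Read a numeric CSV table against a column schema
#'
#' UTF-8, '.' decimal separator.  All schema columns must be present;
#' non-numeric cells are reported with their row and column
#' coordinates.
#'
#' @param path CSV file path.
#' @param schema Character vector of required column names (`NULL` to
#'   accept any header).
#' @return data.frame of numeric columns.
#' @export
read_csv_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  if (!is.null(schema)) {
    miss <- setdiff(schema, names(df))
    if (length(miss))
      stop("missing column(s) in ", path, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop("non-numeric cell at row ", bad[1], ", column '", col, "' in ",
           path, call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Write a numeric table as CSV (12 significant digits)
#'
#' Round-trip stable with [read_csv_table()] for finite values.
#'
#' @param df data.frame of numeric columns.
#' @param path Output path.
#' @export
write_csv_table <- function(df, path) {
  out <- as.data.frame(lapply(df, function(x)
    formatC(x, digits = 12, format = "g")), check.names = FALSE,
    optional = TRUE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read an I-V recording as CSV plus JSON sidecar
#'
#' The CSV carries `time_s` and one `v_<mV>` column per voltage step;
#' the sidecar (same path with extension `.json`) records the light
#' window, sampling rate and junction flag.
#'
#' @param rec An [iv_recording()].
#' @param path CSV path.
#' @return `path`, invisibly (writer); an [iv_recording()] (reader).
#' @export
write_iv_csv <- function(rec, path) {
  stopifnot(inherits(rec, "iv_recording"))
  df <- data.frame(time_s = rec$time_s, rec$currents_pa)
  names(df) <- c("time_s", paste0("v_", rec$voltages_mv))
  write_csv_table(df, path)
  meta <- list(voltages_mv = rec$voltages_mv, light_on_s = rec$light_on_s,
               light_off_s = rec$light_off_s, sampling_hz = rec$sampling_hz,
               junction_corrected = rec$junction_corrected)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_iv_csv
#' @param path CSV path written by [write_iv_csv()].
#' @export
read_iv_csv <- function(path) {
  df <- read_csv_table(path, schema = "time_s")
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path),
                                     ".json"), simplifyVector = TRUE)
  vcols <- grep("^v_", names(df), value = TRUE)
  v <- as.numeric(sub("^v_", "", vcols))
  iv_recording(df$time_s, v, as.matrix(df[vcols]), meta$light_on_s,
               meta$light_off_s, meta$sampling_hz,
               junction_corrected = isTRUE(meta$junction_corrected))
}

#' Write / read a transient-absorption cube as CSV
#'
#' First column `wavelength_nm`, remaining columns named by their time
#' in seconds (`t_<s>`).
#'
#' @param cube A [ta_cube()].
#' @param path CSV path.
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "ta_cube"))
  df <- data.frame(wavelength_nm = cube$wavelengths_nm, cube$delta_a)
  names(df) <- c("wavelength_nm",
                 paste0("t_", formatC(cube$times_s, digits = 12,
                                      format = "g")))
  write_csv_table(df, path)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  df <- read_csv_table(path, schema = "wavelength_nm")
  tcols <- grep("^t_", names(df), value = TRUE)
  times <- as.numeric(sub("^t_", "", tcols))
  ta_cube(df$wavelength_nm, times, as.matrix(df[tcols]))
}

#' Write / read a photocycle scheme as JSON
#'
#' JSON with `species`, `edges` (list of `{from, to, rate_s1}` with
#' `null` rate marking a free parameter placeholder, stored as 1) and
#' `init` populations.
#'
#' @param scheme A [photocycle_scheme()].
#' @param path JSON path.
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "photocycle_scheme"))
  e <- which(scheme$rates > 0, arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(e)), function(i)
    list(from = scheme$species[e[i, 1]], to = scheme$species[e[i, 2]],
         rate_s1 = scheme$rates[e[i, 1], e[i, 2]]))
  g <- scheme$init[setdiff(scheme$species, "ground")]
  jsonlite::write_json(list(species = scheme$species, edges = edges,
                            init = as.list(g)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp <- unlist(j$species)
  n <- length(sp)
  K <- matrix(0, n, n, dimnames = list(sp, sp))
  for (e in j$edges) {
    r <- if (is.null(e$rate_s1)) 1 else e$rate_s1   # null = free placeholder
    K[e$from, e$to] <- r
  }
  init <- unlist(j$init)
  photocycle_scheme(sp, K, init)
}

#' Read a PDB file as a trajectory topology (single frame)
#'
#' Parses ATOM/HETATM records (fixed columns, 1-based residue numbers)
#' into the atom table and one coordinate frame.
#'
#' @param path PDB file path.
#' @return A [trajectory_bundle()] with one frame.
#' @export
read_pdb_topology <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  atoms <- data.frame(index = seq_len(nrow(at)),
                      name = at$elety, resname = at$resid,
                      resno = at$resno,
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                                       substr(trimws(at$elety), 1, 1),
                                       trimws(at$elesy)),
                      stringsAsFactors = FALSE)
  coords <- array(c(at$x, at$y, at$z), c(nrow(at), 3, 1))
  trajectory_bundle(atoms, coords)
}

#' Read concatenated XYZ coordinate frames
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` line per atom; frames concatenated.  The atom count
#' must match the topology in every frame.
#'
#' @param path XYZ file path.
#' @param n_atoms Expected atom count.
#' @return Numeric array `n_atoms x 3 x n_frames`.
#' @export
read_xyz_frames <- function(path, n_atoms) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  per <- n_atoms + 2
  if (length(lines) %% per != 0)
    stop("truncated XYZ file: ", length(lines), " lines is not a multiple ",
         "of ", per, " (", n_atoms, " atoms + 2 header lines)",
         call. = FALSE)
  n_frames <- length(lines) %/% per
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    block <- lines[((f - 1) * per + 1):(f * per)]
    cnt <- suppressWarnings(as.integer(trimws(block[1])))
    if (is.na(cnt) || cnt != n_atoms)
      stop("frame ", f, " declares ", block[1], " atoms; expected ",
           n_atoms, call. = FALSE)
    for (a in seq_len(n_atoms)) {
      tok <- strsplit(trimws(block[2 + a]), "\\s+")[[1]]
      coords[a, , f] <- as.numeric(tok[2:4])
    }
  }
  if (any(!is.finite(coords)))
    stop("non-numeric coordinates in ", path, call. = FALSE)
  coords
}

#' Write XYZ frames
#'
#' @param traj A [trajectory_bundle()].
#' @param path Output path.
#' @export
write_xyz_frames <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_bundle"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(nrow(traj$atoms)), con)
    writeLines(paste("frame", f), con)
    xyz <- .frame_xyz(traj, seq_len(nrow(traj$atoms)), f)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$element,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Write / verify an output manifest with checksums
#'
#' @param files Character vector of file paths.
#' @param path Manifest JSON path.
#' @param truth_ref Optional path of the ground-truth record for
#'   synthetic inputs.
#' @export
write_manifest <- function(files, path, truth_ref = NULL) {
  entries <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(list(tool = "kcrkit",
                            version = as.character(
                              utils::packageVersion("kcrkit")),
                            timestamp = format(Sys.time(), tz = "UTC"),
                            truth_ref = truth_ref, files = entries),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @param dir Directory holding the listed files.
#' @return TRUE when all checksums verify; otherwise an error naming the
#'   first mismatch.
#' @export
verify_manifest <- function(path, dir = dirname(path)) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (e in m$files) {
    f <- file.path(dir, e$file)
    if (!file.exists(f)) stop("manifest file missing: ", f, call. = FALSE)
    if (!identical(unname(tools::md5sum(f)), e$md5))
      stop("checksum mismatch for ", f, call. = FALSE)
  }
  TRUE
}

# recognised run-config keys, checked before execution
.CONFIG_KEYS <- c("input", "output_dir", "solutions", "scheme", "cutoffs",
                  "seed", "log_level", "measure", "n_exp", "windows",
                  "epsilon", "light_on_s", "light_off_s", "p_cl")

#' Validate and resolve a run configuration
#'
#' Rejects unknown keys so typos fail before execution rather than being
#' silently ignored.
#'
#' @param config Named list (e.g. from JSON).
#' @return The validated config with a `seed` default filled in.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- DEFAULT_SEED
  config
}
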