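# File formats: extended XYZ for structures (with per-atom output columns)
# and a plain whitespace table for per-element Qeq parameters. Files default
# to Angstrom lengths (ecosystem convention); everything is converted to
# bohr on read and back on write. A `units=bohr` declaration in the comment
# line (or the `units` argument) switches a file to bohr.

parse_kv_line <- function(line) {
  # key=value tokens; values may be quoted ("..." keeps spaces)
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|[^ \t]+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    tok <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

#' Read a periodic structure from an extended-XYZ file
#'
#' Requires a `Lattice="ax ay az bx by bz cx cy cz"` record in the comment
#' line (the periodic cell is mandatory); an optional `total_charge=...`
#' field sets Q_tot (default 0). Lengths in the file are Angstrom by default
#' and are converted to bohr with the factor 1.8897261254578281; pass
#' `units = "bohr"` (or declare `units=bohr` in the file) for files already
#' in bohr.
#'
#' @param path file path.
#' @param units "angstrom" (default) or "bohr"; a `units=` field in the file
#'   overrides this argument.
#' @return an [atomic_system()] (positions and lattice in bohr).
#' @export
read_xyz <- function(path, units = c("angstrom", "bohr")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("read_xyz: no such structure file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("read_xyz: ", path, ": truncated file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("read_xyz: ", path, " line 1: expected a positive atom count, got '",
         trimws(lines[1]), "'")
  if (length(lines) < n + 2L)
    stop("read_xyz: ", path, ": expected ", n, " atom records, file has ",
         length(lines) - 2L)
  kv <- parse_kv_line(lines[2])
  if (is.null(kv$Lattice))
    stop("read_xyz: ", path, " line 2: missing mandatory Lattice=\"...\" record ",
         "(periodic cell required)")
  lat <- suppressWarnings(as.numeric(strsplit(trimws(kv$Lattice), "[ \t]+")[[1]]))
  if (length(lat) != 9L || anyNA(lat))
    stop("read_xyz: ", path, " line 2: Lattice must contain 9 numbers")
  if (!is.null(kv$units)) {
    if (!kv$units %in% c("angstrom", "bohr"))
      stop("read_xyz: ", path, " line 2: units must be 'angstrom' or 'bohr'")
    units <- kv$units
  }
  qtot <- if (is.null(kv$total_charge)) 0 else as.numeric(kv$total_charge)
  sp <- character(n); pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 2L]), "[ \t]+")[[1]]
    if (length(toks) < 4L)
      stop("read_xyz: ", path, " line ", i + 2L, ": expected 'element x y z ...'")
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(xyz))
      stop("read_xyz: ", path, " line ", i + 2L, ": non-numeric coordinates")
    sp[i] <- toks[1]; pos[i, ] <- xyz
  }
  # extended XYZ stores lattice vectors as rows ax ay az / bx by bz / cx cy cz;
  # internally columns are lattice vectors
  h <- t(matrix(lat, 3, 3, byrow = TRUE))
  f <- if (units == "angstrom") ANGSTROM_IN_BOHR else 1
  atomic_system(h * f, sp, pos * f, qtot)
}

#' Write a structure (with optional per-atom results) to extended XYZ
#'
#' @param path output path.
#' @param system an [atomic_system()] (bohr internally).
#' @param charges optional per-atom charges column (e).
#' @param forces optional N x 3 force columns (hartree/bohr; written as-is,
#'   no unit conversion of derivative quantities is attempted).
#' @param units unit of the written lengths: "angstrom" (default) or "bohr";
#'   declared in the comment line.
#' @return invisibly, the path.
#' @export
write_xyz <- function(path, system, charges = NULL, forces = NULL,
                      units = c("angstrom", "bohr")) {
  units <- match.arg(units)
  f <- if (units == "angstrom") 1 / ANGSTROM_IN_BOHR else 1
  h <- system$lattice * f
  lat <- paste(sprintf("%.17g", as.numeric(t(h))), collapse = " ")
  props <- "species:S:1:pos:R:3"
  cols <- cbind(format(system$positions[, 1] * f, digits = 17),
                format(system$positions[, 2] * f, digits = 17),
                format(system$positions[, 3] * f, digits = 17))
  if (!is.null(charges)) {
    props <- paste0(props, ":charge:R:1")
    cols <- cbind(cols, format(as.numeric(charges), digits = 17))
  }
  if (!is.null(forces)) {
    props <- paste0(props, ":force:R:3")
    cols <- cbind(cols, format(forces[, 1], digits = 17),
                  format(forces[, 2], digits = 17), format(forces[, 3], digits = 17))
  }
  comment <- sprintf('Lattice="%s" Properties=%s units=%s total_charge=%.17g',
                     lat, props, units, system$total_charge)
  body <- paste(system$species, apply(cols, 1, paste, collapse = " "))
  writeLines(c(as.character(system$n_atoms), comment, body), path)
  invisible(path)
}

#' Read per-element Qeq parameters from a plain table
#'
#' Whitespace-separated table with a header line
#' `element chi hardness sigma e_offset` (e_offset optional, `#` comments
#' allowed). Units: hartree/e, hartree/e^2, bohr, hartree.
#'
#' @param path file path.
#' @return a [qeq_parameters()] set.
#' @export
read_qeq_params <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("element", "chi", "hardness", "sigma")
  if (!all(need %in% names(df)))
    stop("read_qeq_params: ", path, ": need columns ", paste(need, collapse = ", "))
  qeq_parameters(df$element, df$chi, df$hardness, df$sigma,
                 e_offset = if ("e_offset" %in% names(df)) df$e_offset else 0)
}

#' Write per-element Qeq parameters
#'
#' @param path output path.
#' @param params a [qeq_parameters()] set.
#' @return invisibly, the path.
#' @export
write_qeq_params <- function(path, params) {
  df <- data.frame(element = params$elements, chi = params$chi,
                   hardness = params$hardness, sigma = params$sigma,
                   e_offset = params$e_offset)
  utils::write.table(format(df, digits = 17), path, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a full result set: extended XYZ plus JSON sidecar
#'
#' Writes `<path>.xyz` with per-atom charge (and force) columns and
#' `<path>.json` with energies, the Lagrange multiplier, solver diagnostics
#' (iterations, residual history), the stress tensor when available, and an
#' echo of the run configuration -- enough to reproduce any reported number.
#'
#' @param path output prefix (without extension).
#' @param system an [atomic_system()].
#' @param result a `qeq_result` from [solve_qeq()] or [direct_solve()].
#' @param derivatives optional list with elements `forces` (N x 3) and/or
#'   `stress` (3x3).
#' @param config optional named list echoed into the sidecar.
#' @param units length unit of the xyz file.
#' @return invisibly, the two paths.
#' @export
write_results <- function(path, system, result, derivatives = NULL,
                          config = NULL, units = c("angstrom", "bohr")) {
  units <- match.arg(units)
  if (!isTRUE(result$converged)) stop("write_results: result is not converged")
  xyz <- paste0(path, ".xyz"); js <- paste0(path, ".json")
  write_xyz(xyz, system, charges = result$charges,
            forces = derivatives$forces, units = units)
  side <- list(e_elec = result$e_elec, e_qeq = result$e_qeq,
               lambda = result$lambda, iterations = result$iterations,
               residual_maxnorm = result$residual_maxnorm,
               residual_history = result$residual_history,
               total_charge = sum(result$charges))
  if (!is.null(derivatives$stress)) {
    s <- derivatives$stress
    side$stress <- 0.5 * (s + t(s))       # written symmetric by construction
  }
  if (!is.null(config)) side$config <- config
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(xyz = xyz, json = js))
}
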