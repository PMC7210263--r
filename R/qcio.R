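#' Readers and writers for the external-engine interface
#'
#' The pipeline consumes exactly five quantities from a geometry-optimization
#' + harmonic-frequency calculation: final electronic energy, converged
#' geometry, harmonic frequencies (imaginary modes printed negative),
#' per-mode Cartesian displacement vectors, and a convergence flag. These are
#' carried in a versioned plain-text log dialect written by
#' [make_mock_optfreq_log()] and read by [parse_optfreq_log()]; string-path
#' outputs (node energies plus transition-state and endpoint geometries) use
#' a parallel dialect. Energies are hartree throughout; conversion to
#' kcal/mol happens only in the energetics layer.
#'
#' @name qcio
NULL

OPTFREQ_HEADER <- "#RXNFORGE-OPTFREQ v1"
STRING_HEADER <- "#RXNFORGE-GSM v1"

#' Read an XYZ geometry block
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` row per atom (Angstrom).
#'
#' @param text Character scalar or vector of lines.
#' @return A list with `elements` (character) and `geometry` (N x 3 matrix).
#' @export
read_xyz <- function(text) {
  lines <- as_lines(text)
  if (length(lines) < 2) stop_rxn("parse", "XYZ: too few lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop_rxn("parse", "XYZ: bad atom count line")
  rows <- lines[-(1:2)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) < n) stop_rxn("parse", "XYZ: atom count exceeds rows present")
  rows <- rows[seq_len(n)]
  parts <- strsplit(trimws(rows), "\\s+")
  if (any(vapply(parts, length, integer(1)) < 4)) {
    stop_rxn("parse", "XYZ: malformed atom row")
  }
  elements <- vapply(parts, `[[`, character(1), 1)
  geometry <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(geometry)) stop_rxn("parse", "XYZ: non-numeric coordinate")
  list(elements = elements, geometry = geometry)
}

#' Write an XYZ geometry block
#'
#' @param elements Character element symbols.
#' @param geometry N x 3 coordinate matrix in Angstrom.
#' @param comment Comment line content.
#' @return A single string (lines joined with newlines).
#' @export
write_xyz <- function(elements, geometry, comment = "") {
  geometry <- as.matrix(geometry)
  stopifnot(nrow(geometry) == length(elements), ncol(geometry) == 3)
  paste(c(
    as.character(length(elements)),
    comment,
    sprintf("%-2s %14.8f %14.8f %14.8f",
            elements, geometry[, 1], geometry[, 2], geometry[, 3])
  ), collapse = "\n")
}

as_lines <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) strsplit(text, "\n")[[1]] else text
}

num_fields <- function(line) as.numeric(strsplit(trimws(line), "\\s+")[[1]])

#' Parse an optimization + frequency log
#'
#' Reads the canonical log dialect (see [make_mock_optfreq_log()]) into an
#' `optfreq_result`. Normal modes are renormalized to unit Euclidean norm on
#' read; imaginary frequencies stay negative. A non-converged marker keeps
#' the record but flags `converged = FALSE`; a missing frequency block is an
#' error -- absent physical quantities are never silently defaulted.
#'
#' @param text Log text (string or lines).
#' @return An `optfreq_result`: list with `elements`, `geometry`, `energy`
#'   (hartree), `frequencies` (cm^-1), `modes` (list of N x 3 matrices),
#'   `converged`, `charge`, `multiplicity`.
#' @export
parse_optfreq_log <- function(text) {
  lines <- as_lines(text)
  if (length(lines) == 0 || trimws(lines[1]) != OPTFREQ_HEADER) {
    stop_rxn("parse", "not an optfreq log (missing header)")
  }
  kv <- function(key) {
    hit <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^", key, " +"), "", hit[1])
  }
  conv <- kv("converged")
  energy <- kv("energy")
  natoms <- kv("natoms")
  if (is.null(energy) || is.null(natoms)) {
    stop_rxn("incomplete_log", "missing energy or natoms")
  }
  n <- as.integer(natoms)
  geo_at <- grep("^geometry$", trimws(lines))
  if (length(geo_at) == 0) stop_rxn("incomplete_log", "missing geometry block")
  geo_rows <- lines[(geo_at[1] + 1):(geo_at[1] + n)]
  if (length(geo_rows) < n || anyNA(geo_rows)) {
    stop_rxn("incomplete_log", "truncated geometry block")
  }
  parts <- strsplit(trimws(geo_rows), "\\s+")
  elements <- vapply(parts, `[[`, character(1), 1)
  geometry <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  nmodes_s <- kv("nmodes")
  freq_at <- grep("^frequencies$", trimws(lines))
  if (is.null(nmodes_s) || length(freq_at) == 0) {
    stop_rxn("incomplete_log", "missing frequency block")
  }
  nm <- as.integer(nmodes_s)
  freqs <- if (nm > 0) num_fields(lines[freq_at[1] + 1]) else numeric(0)
  if (length(freqs) != nm || anyNA(freqs)) {
    stop_rxn("incomplete_log", "frequency count mismatch")
  }
  modes <- vector("list", nm)
  for (k in seq_len(nm)) {
    mode_at <- grep(paste0("^mode ", k, "$"), trimws(lines))
    if (length(mode_at) == 0) stop_rxn("incomplete_log", "missing mode block")
    rows <- lines[(mode_at[1] + 1):(mode_at[1] + n)]
    mm <- t(vapply(strsplit(trimws(rows), "\\s+"),
                   function(p) as.numeric(p[1:3]), numeric(3)))
    if (anyNA(mm)) stop_rxn("incomplete_log", "truncated mode block")
    nrm <- sqrt(sum(mm^2))
    if (nrm == 0) stop_rxn("parse", "zero-norm mode vector")
    modes[[k]] <- mm / nrm
  }
  structure(list(
    elements = elements, geometry = geometry,
    energy = as.numeric(energy),
    frequencies = freqs, modes = modes,
    converged = identical(conv, "true"),
    charge = as.integer(kv("charge") %||% "0"),
    multiplicity = as.integer(kv("multiplicity") %||% "1")
  ), class = "optfreq_result")
}

#' @export
print.optfreq_result <- function(x, ...) {
  n_imag <- sum(x$frequencies < 0)
  cat(sprintf("<optfreq_result> %d atoms, E = %.6f Eh, %d modes (%d imaginary)%s\n",
              length(x$elements), x$energy, length(x$frequencies), n_imag,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Write an optimization + frequency log
#'
#' Fixture generator emulating the external engine's output in the canonical
#' dialect; [parse_optfreq_log()] recovers every field at printed precision.
#'
#' @param energy Electronic energy, hartree.
#' @param elements Element symbols.
#' @param geometry N x 3 matrix, Angstrom.
#' @param frequencies Harmonic frequencies in cm^-1, imaginary as negative.
#' @param modes List of N x 3 Cartesian displacement matrices, one per
#'   frequency (any nonzero scale; normalized on read).
#' @param converged Convergence flag.
#' @param charge,multiplicity Pass-through metadata.
#' @return Log text as one string.
#' @export
make_mock_optfreq_log <- function(energy, elements, geometry, frequencies,
                                  modes, converged = TRUE,
                                  charge = 0L, multiplicity = 1L) {
  geometry <- as.matrix(geometry)
  if (length(frequencies) != length(modes)) {
    stop_rxn("spec", "mode count must equal frequency count")
  }
  if (nrow(geometry) != length(elements)) {
    stop_rxn("spec", "geometry row count must equal element count")
  }
  out <- c(
    OPTFREQ_HEADER,
    paste("converged", if (converged) "true" else "false"),
    paste("charge", charge),
    paste("multiplicity", multiplicity),
    sprintf("energy %.10f", energy),
    paste("natoms", length(elements)),
    "geometry",
    sprintf("%-2s %14.8f %14.8f %14.8f",
            elements, geometry[, 1], geometry[, 2], geometry[, 3]),
    paste("nmodes", length(frequencies)),
    "frequencies",
    if (length(frequencies) > 0)
      paste(sprintf("%.4f", frequencies), collapse = " ") else "",
    unlist(lapply(seq_along(modes), function(k) {
      mm <- as.matrix(modes[[k]])
      if (nrow(mm) != length(elements)) {
        stop_rxn("spec", "mode row count must equal atom count")
      }
      c(paste("mode", k),
        sprintf("%14.8f %14.8f %14.8f", mm[, 1], mm[, 2], mm[, 3]))
    })),
    "end"
  )
  paste(out, collapse = "\n")
}

#' Parse a string-path (growing-string) output file
#'
#' @param text Output text in the canonical string-path dialect.
#' @return A `string_path`: list with `node_energies` (hartree),
#'   `ts_node_index` (1-based index of the highest-energy node, first
#'   occurrence on ties), `ts_geometry` and `endpoint_geometry` (N x 3),
#'   `elements`.
#' @export
parse_string_output <- function(text) {
  lines <- as_lines(text)
  if (length(lines) == 0 || trimws(lines[1]) != STRING_HEADER) {
    stop_rxn("parse", "not a string-path output (missing header)")
  }
  kv <- function(key) {
    hit <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (length(hit) == 0) NULL else sub(paste0("^", key, " +"), "", hit[1])
  }
  nn <- as.integer(kv("nnodes") %||% stop_rxn("parse", "missing nnodes"))
  e_at <- grep("^energies$", trimws(lines))
  if (length(e_at) == 0) stop_rxn("parse", "missing energies block")
  energies <- num_fields(lines[e_at[1] + 1])
  if (length(energies) != nn || anyNA(energies)) {
    stop_rxn("parse", "node energy count mismatch")
  }
  if (nn < 2) stop_rxn("degenerate_path", "string path needs at least 2 nodes")
  n <- as.integer(kv("natoms") %||% stop_rxn("parse", "missing natoms"))
  read_block <- function(name) {
    at <- grep(paste0("^", name, "$"), trimws(lines))
    if (length(at) == 0) stop_rxn("parse", paste("missing", name, "block"))
    rows <- lines[(at[1] + 1):(at[1] + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    list(elements = vapply(parts, `[[`, character(1), 1),
         geometry = t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))))
  }
  ts <- read_block("ts_geometry")
  ep <- read_block("endpoint_geometry")
  structure(list(
    node_energies = energies,
    ts_node_index = which.max(energies),
    ts_geometry = ts$geometry,
    endpoint_geometry = ep$geometry,
    elements = ts$elements
  ), class = "string_path")
}

#' Write a string-path output file
#'
#' Fixture generator emulating the path-search driver's per-path output.
#'
#' @param node_energies Energies along the path, hartree (>= 2 nodes).
#' @param elements Element symbols.
#' @param ts_geometry Geometry of the highest-energy node, N x 3.
#' @param endpoint_geometry Geometry of the final node, N x 3.
#' @return Output text as one string.
#' @export
make_mock_string_output <- function(node_energies, elements, ts_geometry,
                                    endpoint_geometry) {
  if (length(node_energies) < 2) {
    stop_rxn("spec", "string path needs at least 2 node energies")
  }
  geom_rows <- function(geometry) {
    geometry <- as.matrix(geometry)
    if (nrow(geometry) != length(elements)) {
      stop_rxn("spec", "geometry row count must equal atom count")
    }
    sprintf("%-2s %14.8f %14.8f %14.8f",
            elements, geometry[, 1], geometry[, 2], geometry[, 3])
  }
  paste(c(
    STRING_HEADER,
    paste("nnodes", length(node_energies)),
    "energies",
    paste(sprintf("%.10f", node_energies), collapse = " "),
    paste("natoms", length(elements)),
    "ts_geometry", geom_rows(ts_geometry),
    "endpoint_geometry", geom_rows(endpoint_geometry),
    "end"
  ), collapse = "\n")
}

#' Engine configuration (level of theory and job settings)
#'
#' @param method Electronic-structure method string, e.g. `"B97-D3"` or
#'   `"wB97X-D3"`; passed through to the engine, never interpreted.
#' @param basis Basis-set string, e.g. `"def2-mSVP"`, `"def2-TZVP"`.
#' @param job_type `"opt+freq"` for minima, `"ts-opt+freq"` for saddles.
#' @param extra Named character list of additional keywords.
#' @return An `engine_config` list.
#' @export
engine_config <- function(method, basis, job_type = c("opt+freq", "ts-opt+freq"),
                          extra = list()) {
  job_type <- match.arg(job_type)
  if (!nzchar(method) || !nzchar(basis)) {
    stop_rxn("config", "method and basis must be non-empty")
  }
  structure(list(method = method, basis = basis, job_type = job_type,
                 extra = extra), class = "engine_config")
}

#' Level tag (method/basis) of an engine configuration
#' @param cfg An `engine_config`.
#' @return String like `"B97-D3/def2-mSVP"`.
#' @export
level_tag <- function(cfg) paste(cfg$method, cfg$basis, sep = "/")

#' Write an engine input file
#'
#' Deterministic text (byte-identical for identical inputs) with a molecule
#' block (charge, multiplicity, coordinates) and a keyword block.
#'
#' @param elements Element symbols.
#' @param geometry N x 3 matrix, Angstrom.
#' @param cfg An [engine_config()].
#' @param charge,multiplicity Molecular charge and spin multiplicity.
#' @return Input text as one string.
#' @export
write_engine_input <- function(elements, geometry, cfg,
                               charge = 0L, multiplicity = 1L) {
  if (!inherits(cfg, "engine_config")) stop_rxn("config", "cfg must be an engine_config")
  geometry <- as.matrix(geometry)
  extra <- if (length(cfg$extra) > 0) cfg$extra[order(names(cfg$extra))] else list()
  paste(c(
    "$molecule",
    sprintf("%d %d", charge, multiplicity),
    sprintf("%-2s %14.8f %14.8f %14.8f",
            elements, geometry[, 1], geometry[, 2], geometry[, 3]),
    "$end",
    "$rem",
    paste("jobtype", cfg$job_type),
    paste("method", cfg$method),
    paste("basis", cfg$basis),
    if (length(extra) > 0) paste(names(extra), unlist(extra)),
    "$end"
  ), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
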