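# Readers and writers: trajectory frames (extended XYZ + JSON sidecar),
# contact matrices and metrics as TSV, and YAML run configuration.

FRAME_XYZ_COLS <- c("species", "x", "y", "z", "bead_bp")

#' Write a trajectory frame
#'
#' Writes `<path>.xyz` (extended XYZ: species, position, genomic bp
#' coordinate; ribosomes carry coordinate -1) and `<path>.json` (sidecar:
#' time, shape, fork state, SMC head pairs, seed). Positions round-trip
#' bit-exactly through [read_frame()].
#'
#' @param frame A trajectory frame (see [run_cell_cycle()]).
#' @param path Output path; any `.xyz`/`.json` extension is stripped.
#' @return The two file paths, invisibly.
#' @export
write_frame <- function(frame, path) {
  base <- sub("\\.(xyz|json)$", "", path)
  n_dna <- nrow(frame$positions)
  n_ribo <- if (is.null(frame$ribosomes)) 0L else nrow(frame$ribosomes)
  pos <- rbind(frame$positions, frame$ribosomes)
  species <- c(frame$species, rep("ribosome", n_ribo))
  bead_bp <- c(frame$bead_bp, rep(-1L, n_ribo))
  lines <- c(
    sprintf("%d", n_dna + n_ribo),
    sprintf("chromocycle frame t=%.17g min columns=%s",
            frame$t, paste(FRAME_XYZ_COLS, collapse = ",")),
    sprintf("%s %.17g %.17g %.17g %d",
            species, pos[, 1], pos[, 2], pos[, 3], bead_bp)
  )
  xyz_path <- paste0(base, ".xyz")
  writeLines(lines, xyz_path)
  sidecar <- list(
    t = frame$t,
    shape = list(
      mode = frame$shape$mode, R = frame$shape$R, d = frame$shape$d,
      axis = frame$shape$axis, center = frame$shape$center
    ),
    fork = frame$fork,
    smc_pairs = if (nrow(frame$smc_pairs) == 0) {
      matrix(integer(0), 0, 2)
    } else frame$smc_pairs,
    seed = frame$seed,
    n_dna_beads = n_dna,
    n_ribosomes = n_ribo
  )
  validate_frame_sidecar(sidecar)
  json_path <- paste0(base, ".json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(xyz = xyz_path, json = json_path))
}

#' Read a trajectory frame
#'
#' @param path Base path used in [write_frame()].
#' @return A `trajectory_frame`.
#' @export
read_frame <- function(path) {
  base <- sub("\\.(xyz|json)$", "", path)
  lines <- readLines(paste0(base, ".xyz"))
  n <- as.integer(lines[1])
  parts <- strsplit(lines[2 + seq_len(n)], " ", fixed = TRUE)
  species <- vapply(parts, `[[`, "", 1)
  pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
                byrow = TRUE)
  bead_bp <- vapply(parts, function(p) as.numeric(p[5]), numeric(1))
  sidecar <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  validate_frame_sidecar(sidecar)
  dna <- species != "ribosome"
  smc_pairs <- matrix(as.integer(unlist(sidecar$smc_pairs)), ncol = 2)
  structure(
    list(
      t = sidecar$t,
      positions = pos[dna, , drop = FALSE],
      species = species[dna],
      bead_bp = as.integer(bead_bp[dna]),
      ribosomes = pos[!dna, , drop = FALSE],
      smc_pairs = smc_pairs,
      shape = cell_shape(sidecar$shape$R, sidecar$shape$d,
                         unlist(sidecar$shape$axis),
                         unlist(sidecar$shape$center)),
      fork = sidecar$fork,
      seed = sidecar$seed
    ),
    class = "trajectory_frame"
  )
}

#' Validate a frame sidecar against the published schema
#'
#' Checks required fields and types per `inst/schema/frame-schema.json`;
#' violations are reported with their field paths.
#'
#' @param sidecar Named list (parsed JSON or pre-write structure).
#' @return `TRUE` invisibly, or an error.
#' @export
validate_frame_sidecar <- function(sidecar) {
  schema <- jsonlite::read_json(
    system.file("schema", "frame-schema.json", package = "chromocycle",
                mustWork = TRUE),
    simplifyVector = FALSE
  )
  errs <- character(0)
  check <- function(obj, sch, path) {
    for (req in unlist(sch$required)) {
      if (is.null(obj[[req]])) {
        errs <<- c(errs, sprintf("missing required field: %s%s", path, req))
      }
    }
    for (nm in names(sch$properties)) {
      val <- obj[[nm]]
      if (is.null(val)) next
      psch <- sch$properties[[nm]]
      ok <- switch(psch$type,
        number = is.numeric(val) && length(val) == 1,
        integer = is.numeric(val) && length(val) == 1 &&
          abs(val - round(val)) < 1e-9,
        boolean = is.logical(val) && length(val) == 1,
        string = is.character(val) && length(val) == 1,
        array = is.numeric(unlist(val)) || length(unlist(val)) == 0,
        object = is.list(val),
        TRUE
      )
      if (!isTRUE(ok)) {
        errs <<- c(errs, sprintf("field %s%s: expected %s", path, nm, psch$type))
      } else if (psch$type == "object") {
        check(val, psch, paste0(path, nm, "."))
      }
    }
  }
  check(sidecar, schema, "")
  if (length(errs) > 0) {
    stop("frame sidecar validation failed:\n  ", paste(errs, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Write / read a contact matrix as TSV
#'
#' Dense tab-separated values with a header row of segment start
#' coordinates (bp).
#'
#' @param m A [contact_matrix()]. @param path Output file.
#' @return The path, invisibly.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  starts <- (seq_len(m$n_segments) - 1L) * m$resolution
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(starts, collapse = "\t"), con)
  utils::write.table(m$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @param kind Matrix kind recorded on read (`"counts"` etc.).
#' @export
read_contact_matrix <- function(path, kind = "counts") {
  header <- scan(path, what = numeric(), nlines = 1, sep = "\t", quiet = TRUE)
  values <- as.matrix(utils::read.table(path, sep = "\t", skip = 1,
                                        header = FALSE))
  dimnames(values) <- NULL
  resolution <- if (length(header) > 1) header[2] - header[1] else 1000
  contact_matrix(values, resolution, kind = kind)
}

#' Write a tidy metrics table as TSV
#'
#' @param df Data frame (e.g. `trajectory$metrics`). @param path Output file.
#' @return The path, invisibly.
#' @export
write_metrics <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a simulation configuration from YAML
#'
#' The file may set `preset`, `seed` and any [sim_config()] field; unknown
#' keys are rejected and preset defaults fill the rest. The full parameter
#' set is echoed with `message()` when `echo = TRUE`.
#'
#' @param path YAML file. @param echo Log the effective configuration.
#' @return A [sim_config()].
#' @export
load_config <- function(path, echo = TRUE) {
  # keep bare single-letter keys like `N:` literal instead of YAML 1.1
  # booleans; yes/no/true/false values still parse as logicals
  raw <- yaml::read_yaml(path, handlers = list(
    `bool#no` = function(x) if (x %in% c("n", "N")) x else FALSE,
    `bool#yes` = function(x) if (x %in% c("y", "Y")) x else TRUE
  ))
  if (is.null(raw)) raw <- list()
  preset <- raw$preset %||% "paper"
  seed <- raw$seed %||% 1L
  raw$preset <- NULL
  raw$seed <- NULL
  cfg <- do.call(sim_config, c(list(preset = preset), raw, list(seed = seed)))
  if (echo) {
    message("configuration: ",
            jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
  }
  cfg
}
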