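trace_columns <- c("time_s", "rotation_turns", "height_um", "mode",
                   "segment_id", "buffer")

validate_trace <- function(tr) {
  errs <- character()
  miss <- setdiff(trace_columns, names(tr))
  if (length(miss)) {
    errs <- c(errs, paste("missing columns:", paste(miss, collapse = ", ")))
  } else {
    for (col in c("time_s", "rotation_turns", "height_um")) {
      if (!is.numeric(tr[[col]])) {
        errs <- c(errs, paste0(col, ": must be numeric"))
      }
    }
    if (is.numeric(tr$height_um) && any(tr$height_um < 0, na.rm = TRUE)) {
      errs <- c(errs, "height_um: negative values")
    }
    if (any(is.na(tr$height_um))) errs <- c(errs, "height_um: NA values")
    bad_mode <- setdiff(unique(as.character(tr$mode)), c("fast", "slow"))
    if (length(bad_mode)) {
      errs <- c(errs, paste("mode: values outside {fast, slow}:",
                            paste(bad_mode, collapse = ", ")))
    }
  }
  errs
}

#' Read and write trace files
#'
#' Traces are tab-separated text with a header row (columns `time_s`,
#' `rotation_turns`, `height_um`, `mode`, `segment_id`, `buffer`), '.'
#' decimal marks and UTF-8 encoding. Lines starting with `#` carry run
#' metadata (seed, config hash) and are skipped on read. The schema is
#' validated exhaustively on read: all violations are reported, not just
#' the first.
#'
#' @param trace An `hj_trace` (or conforming data frame).
#' @param path File path.
#' @param metadata Optional named list written as `# key: value` comment
#'   lines.
#' @return `read_trace` returns an `hj_trace` data frame; `write_trace`
#'   returns `path` invisibly.
#' @export
write_trace <- function(trace, path, metadata = NULL) {
  errs <- validate_trace(trace)
  if (length(errs)) {
    stop("invalid trace:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- list(seed = attr(trace, "seed"))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(metadata)) {
    if (!is.null(metadata[[k]])) {
      writeLines(sprintf("# %s: %s", k, format(metadata[[k]])), con)
    }
  }
  write.table(as.data.frame(trace)[trace_columns], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tr <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  errs <- validate_trace(tr)
  if (length(errs)) {
    stop("invalid trace file '", path, "':\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  structure(tr, class = c("hj_trace", "data.frame"))
}

#' Read arm sequences from a FASTA file
#'
#' Standard multi-line FASTA; lowercase bases are accepted and upcased.
#' The first two records become the two arms of an [arm_pair()].
#'
#' @param path FASTA file with at least two records.
#' @return An `arm_pair`.
#' @export
read_fasta_arms <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 2) {
    stop("FASTA must contain at least two sequences (the two arms)",
         call. = FALSE)
  }
  arm_pair(toupper(as.character(ss[[1]])), toupper(as.character(ss[[2]])),
           label_a = names(ss)[1], label_b = names(ss)[2])
}

#' Write a mismatch table as TSV
#' @param table A `mismatch_table`.
#' @param path Output path.
#' @param metadata Optional named list written as comment lines.
#' @return `path`, invisibly.
#' @export
write_mismatch_table <- function(table, path, metadata = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("# %s: %s", k, format(metadata[[k]])), con)
  }
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    sim = list(N0 = 1200, H0 = 2.76, hr_dna = 10.45, plecto_width = 0.025,
               noise_sd_slow = 0.035, noise_sd_fast = 0.105,
               skid_prob = 0, skid_magnitude_range = c(1, 5),
               temperature = 37, force = 0.2),
    design = list(length = 800, divergence = 0.01, indel_rate = 0,
                  offset_to_center = 2200),
    protocol = list(R_start = -420, R_stop = -580, fast_span = 14,
                    slow_span = 25, restart_step = 2),
    analysis = list(n_pieces = 8, resolution = 2, n_boot = 200,
                    detector_k = 3),
    constants = list(hr_dna = 10.45, kbT = 4.14, C = 95,
                     rise_per_bp = 0.30),
    seed = 1
  )
}

#' Read and validate a run configuration
#'
#' JSON run configuration with sections `sim`, `design`, `protocol`,
#' `analysis`, `constants` and a top-level `seed`; missing entries take
#' package defaults, and schema violations are reported exhaustively with
#' their JSON paths.
#'
#' @param path JSON file, or `NULL` for the package defaults.
#' @return A named list (the validated configuration) with attribute
#'   `hash`, an MD5 digest of the canonical JSON serialization.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    known <- names(cfg)
    unknown <- setdiff(names(user), known)
    errs <- if (length(unknown)) {
      paste0("$", unknown, ": unknown section")
    } else character()
    for (sec in intersect(names(user), known)) {
      if (sec == "seed") { cfg$seed <- user$seed; next }
      bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      errs <- c(errs, if (length(bad)) paste0("$", sec, ".", bad,
                                              ": unknown field"))
      cfg[[sec]] <- modifyList(cfg[[sec]],
                               user[[sec]][setdiff(names(user[[sec]]), bad)])
    }
    errs <- c(errs, validate_config(cfg))
    if (length(errs)) {
      stop("invalid configuration '", path, "':\n  ",
           paste(errs, collapse = "\n  "), call. = FALSE)
    }
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

validate_config <- function(cfg) {
  errs <- character()
  pos <- function(sec, fld) {
    v <- cfg[[sec]][[fld]]
    if (!is.numeric(v) || any(v <= 0)) {
      errs <<- c(errs, paste0("$", sec, ".", fld, ": must be > 0"))
    }
  }
  pos("sim", "N0"); pos("sim", "H0"); pos("sim", "hr_dna")
  pos("analysis", "n_pieces"); pos("analysis", "resolution")
  pos("constants", "kbT"); pos("constants", "C"); pos("constants",
                                                      "rise_per_bp")
  if (!(cfg$protocol$R_start > cfg$protocol$R_stop)) {
    errs <- c(errs, "$protocol: R_start must exceed R_stop")
  }
  if (cfg$design$divergence < 0 || cfg$design$divergence >= 1) {
    errs <- c(errs, "$design.divergence: must be in [0, 1)")
  }
  errs
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

sim_params_from_config <- function(cfg) {
  s <- cfg$sim
  sim_params(N0 = s$N0, H0 = s$H0, hr_dna = s$hr_dna,
             plecto_width = s$plecto_width,
             noise_sd_slow = s$noise_sd_slow,
             noise_sd_fast = s$noise_sd_fast,
             skid_prob = s$skid_prob,
             skid_magnitude_range = s$skid_magnitude_range,
             temperature = s$temperature, force = s$force,
             seed = cfg$seed)
}

#' Run the full simulate-and-map pipeline
#'
#' Executes every stage on a configuration: generates a synthetic homolog
#' pair and its mismatch table, simulates the reference-curve acquisition
#' and the go-and-return mapping run, estimates `N0` from the
#' migration-regime points, fits the reference curve, detects and fits the
#' blockage curve-segments (with bootstrap errors), and matches fitted to
#' expected blockage rotations. When `out_dir` is given, each stage writes
#' its artifact (TSV/JSON, every file carrying the seed and config hash).
#'
#' @param config A configuration from [read_config()] (`NULL` for
#'   defaults).
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return A list with `arms`, `mismatch_table` (after resolution merging),
#'   `trace`, `ref`, `fits`, and `map`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.null(config)) read_config(NULL) else config
  hash <- attr(cfg, "hash")
  if (is.null(hash)) hash <- config_hash(cfg)
  meta <- list(seed = cfg$seed, config_md5 = hash)
  say <- function(...) if (!quiet) message(sprintf(...))

  params <- sim_params_from_config(cfg)
  hr <- cfg$constants$hr_dna

  say("design: synthetic homolog pair (%d bp, %.1f%% divergence)",
      cfg$design$length, 100 * cfg$design$divergence)
  arms <- make_synthetic_homologs(cfg$design$length, cfg$design$divergence,
                                  cfg$design$indel_rate, seed = cfg$seed)
  tab <- find_differences(arms, cfg$design$offset_to_center, hr_dna = hr)
  tab_merged <- merge_unresolvable(tab, cfg$analysis$resolution)

  say("simulate: mapping run over R in [%g, %g]",
      cfg$protocol$R_stop, cfg$protocol$R_start)
  trace <- simulate_protocol_run(params, tab$base_index,
                                 R_start = cfg$protocol$R_start,
                                 R_stop = cfg$protocol$R_stop,
                                 fast_span = cfg$protocol$fast_span,
                                 slow_span = cfg$protocol$slow_span,
                                 restart_step = cfg$protocol$restart_step)
  ref_trace <- simulate_reference_trace(params)

  say("reference: N0 / H0 estimation and spline fit")
  mig <- trace[trace$segment_id == 0, , drop = FALSE]
  n0 <- estimate_N0(mig)
  ref <- fit_reference(ref_trace, N0 = n0$N0,
                       n_pieces = cfg$analysis$n_pieces)

  say("blockages: detect, fit, bootstrap (%d reps)", cfg$analysis$n_boot)
  fits <- fit_blockages(trace, ref, k = cfg$analysis$detector_k,
                        n_boot = cfg$analysis$n_boot, seed = cfg$seed)
  if (length(fits) < 2) {
    stop("fewer than 2 blockage segments detected; nothing to map",
         call. = FALSE)
  }

  say("map: match fitted to expected rotations")
  scanned <- tab_merged$expected_rotation <= cfg$protocol$R_start &
    tab_merged$expected_rotation >= cfg$protocol$R_stop
  map <- match_and_calibrate(fits, tab_merged[scanned, , drop = FALSE],
                             hr_dna = hr)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "arms.fasta")
    writeLines(c(paste0(">", arms$label_a), arms$seq_a,
                 paste0(">", arms$label_b), arms$seq_b), fa)
    write_mismatch_table(tab, file.path(out_dir, "mismatches.tsv"), meta)
    write_trace(trace, file.path(out_dir, "trace.tsv"), meta)
    write_trace(ref_trace, file.path(out_dir, "reference_trace.tsv"), meta)
    write_refcurve(ref, file.path(out_dir, "reference_curve.json"))
    fit_tab <- data.frame(
      segment_id = vapply(fits, `[[`, 0L, "segment_id"),
      Ri = vapply(fits, `[[`, 0, "Ri"),
      Ni = vapply(fits, `[[`, 0, "Ni"),
      boot_sd = vapply(fits, `[[`, 0, "boot_sd"),
      boot_bias = vapply(fits, `[[`, 0, "boot_bias"),
      converged = vapply(fits, `[[`, TRUE, "converged"),
      n_points_used = vapply(fits, `[[`, 0L, "n_points"))
    write_mismatch_table(fit_tab, file.path(out_dir, "blockage_fits.tsv"),
                         meta)
    report <- c(meta,
                list(A = map$A, sd_turns = map$sd_turns,
                     sd_bases = map$sd_bases, n_matched = map$n_matched,
                     gap = signature_gap(tab_merged),
                     N0 = n0$N0, H0 = ref$H0))
    jsonlite::write_json(report, file.path(out_dir, "map_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_mismatch_table(map$pairs, file.path(out_dir, "map_pairs.tsv"),
                         meta)
  }
  invisible(list(arms = arms, mismatch_table = tab_merged, trace = trace,
                 ref = ref, fits = fits, map = map, config = cfg))
}
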