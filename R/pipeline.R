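# Reproducible pipeline entry points: a validated configuration, a
# run_pipeline() dispatcher over the analysis stages, and a small CLI
# (shm_cli(), wrapped by exec/shm) mirroring every threshold.

CONFIG_DEFAULTS <- list(
  subcommand = NULL,        # simulate | repertoire | mutpe | traj
  seed = 1L,
  out_dir = ".",
  log_level = "info",
  # repertoire analysis (published defaults)
  k = 15L,                  # C-centred context window
  min_coverage = 30L,       # groups below this coverage are excluded
  pypy_mode = "wrch5",      # PyPy segment: motif +/- 5 bp
  wrch_only = TRUE,
  # amplicon quantification (published defaults)
  trim_window = 5L, trim_min_q = 25,
  min_len_r1 = 200L, min_len_r2 = 100L,
  max_mismatch_fraction = 0.10, min_overlap = 10L,
  length_tolerance = 30L, max_mismatch_rate = 0.15, min_base_q = 30,
  primer_clip_5p = 0L,
  # simulator
  n_sequences = 1000L, depth = 1000L, error_rate = 0.001,
  read_len_r1 = 250L, read_len_r2 = 180L,
  # traj
  superpose = TRUE, center_mode = "centroid",
  # io
  input = NULL, input2 = NULL, reference = NULL, regions = NULL
)

#' Build a validated run configuration
#'
#' Starts from the package defaults -- each analysis threshold defaults
#' to its published value (Q25 over a 5-nt window, 200/100 nt mate
#' minima, 10% overlap mismatch, +/-30 nt length gate, Q30 pileup,
#' coverage 30, k = 15, PyPy over the motif +/-5 bp segment) -- and
#' applies named overrides. Unknown keys are an error naming the key.
#'
#' @param subcommand One of `"simulate"`, `"repertoire"`, `"mutpe"`,
#'   `"traj"`.
#' @param ... Named overrides of any default in `run_config()$defaults`.
#' @return List of class `shm_config`.
#' @export
run_config <- function(subcommand = c("simulate", "repertoire", "mutpe", "traj"),
                       ...) {
  subcommand <- match.arg(subcommand)
  cfg <- CONFIG_DEFAULTS
  cfg$subcommand <- subcommand
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    stop("config overrides must be named", call. = FALSE)
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown config key: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("config key 'seed' must be an integer", call. = FALSE)
  structure(cfg, class = "shm_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run a configured pipeline stage
#'
#' Dispatches on `config$subcommand`, writes the stage's artifacts
#' under `config$out_dir` and a structured `run_log.json` recording the
#' package version, the config (and its hash), the seed and per-stage
#' tallies. Deterministic given the seed. On failure, partial outputs
#' of the run are removed.
#'
#' * `simulate`: germline FASTA, repertoire TSV, truth-rate TSV and
#'   paired FASTQ mates from the default B1-8hi-like layout.
#' * `repertoire`: context groups, per-level mutability/correlation and
#'   subregion tables from a repertoire TSV (`input`, optional
#'   `regions` sidecar).
#' * `mutpe`: per-position (normalized) profile TSV plus run log from
#'   FASTQ mates (`input`, `input2`) and a FASTA reference
#'   (`reference`).
#' * `traj`: Rg, RMSF and Delta_s TSV profiles from a multi-model PDB
#'   (`input`).
#'
#' @param config An `shm_config` from [run_config()].
#' @return Invisibly, a list with `artifacts` (paths) and `log`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "shm_config")) {
    stop("config must come from run_config()", call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0L)
  cleanup <- function() if (length(artifacts)) unlink(artifacts)
  res <- tryCatch({
    switch(config$subcommand,
      simulate = {
        germ <- make_germline(b18_layout(), seed = config$seed)
        model <- mutation_model()
        rep <- simulate_repertoire(germ, model, config$n_sequences,
                                   seed = config$seed + 1L)
        pool <- unique(rep$observed)
        reads <- simulate_read_pairs(
          pool, read_sim_config(read_len_r1 = config$read_len_r1,
                                read_len_r2 = config$read_len_r2,
                                error_rate = config$error_rate,
                                depth = config$depth,
                                seed = config$seed + 2L))
        paths <- file.path(out_dir, c("germline.fa", "repertoire.tsv",
                                      "site_rates.tsv", "reads_R1.fastq",
                                      "reads_R2.fastq"))
        artifacts <- paths
        write_fasta(c(germline = germ$sequence), paths[1L])
        fwrite(as.data.table(rep), paths[2L], sep = "\t")
        fwrite(attr(rep, "truth"), paths[3L], sep = "\t")
        write_fastq(reads$r1, paths[4L])
        write_fastq(reads$r2, paths[5L])
        list(tally = c(n_sequences = nrow(rep), read_pairs = config$depth))
      },
      repertoire = {
        if (is.null(config$input)) stop("config key 'input' is required",
                                        call. = FALSE)
        rec <- read_repertoire_tsv(config$input, config$regions)
        groups <- build_context_groups(rec, k = config$k,
                                       wrch_only = config$wrch_only,
                                       pypy_mode = config$pypy_mode)
        kept <- filter_coverage(groups, config$min_coverage)
        paths <- file.path(out_dir, c("context_groups.tsv",
                                      "mutability_by_pypy.tsv"))
        artifacts <- paths
        fwrite(kept, paths[1L], sep = "\t")
        lev <- rbindlist(lapply(split(kept[!is.na(kept$motif)], by = "motif"),
                                function(g) {
          r <- mutability_by_pypy(g)
          cbind(motif = r$motif, r$levels, r = r$r, r_squared = r$r_squared)
        }))
        fwrite(lev, paths[2L], sep = "\t")
        if (!is.null(attr(rec, "region_map"))) {
          p3 <- file.path(out_dir, "subregion_summary.tsv")
          artifacts <- c(artifacts, p3)
          fwrite(subregion_summary(rec, wrch_only = config$wrch_only), p3,
                 sep = "\t")
        }
        list(tally = c(records = nrow(rec), groups = nrow(groups),
                       groups_kept = nrow(kept)))
      },
      mutpe = {
        for (key in c("input", "input2", "reference")) {
          if (is.null(config[[key]])) {
            stop("config key '", key, "' is required", call. = FALSE)
          }
        }
        r1 <- read_fastq(config$input)
        r2 <- read_fastq(config$input2)
        ref <- read_fasta(config$reference)[[1L]]
        mcfg <- mutpe_config(
          trim_window = config$trim_window, trim_min_q = config$trim_min_q,
          min_len_r1 = config$min_len_r1, min_len_r2 = config$min_len_r2,
          max_mismatch_fraction = config$max_mismatch_fraction,
          min_overlap = config$min_overlap,
          length_tolerance = config$length_tolerance,
          max_mismatch_rate = config$max_mismatch_rate,
          min_base_q = config$min_base_q,
          primer_clip_5p = config$primer_clip_5p)
        run <- mutpe_run(r1, r2, ref, mcfg)
        p <- file.path(out_dir, "profile.tsv")
        artifacts <- p
        write_profile_tsv(run$profile, p)
        list(tally = run$tally)
      },
      traj = {
        if (is.null(config$input)) stop("config key 'input' is required",
                                        call. = FALSE)
        traj <- read_pdb_trajectory(config$input)
        prot <- select_atoms(traj, chain = "protein")
        rg <- vapply(seq_len(n_frames(traj)), function(t) {
          radius_of_gyration(frame_coords(traj, t)[prot, , drop = FALSE])
        }, numeric(1L))
        paths <- file.path(out_dir, c("rg.tsv", "rmsf.tsv", "delta_s.tsv"))
        artifacts <- paths
        fwrite(data.table(frame = seq_along(rg), rg = rg), paths[1L], sep = "\t")
        fwrite(rmsf(traj, superpose = config$superpose, grouping = "residue"),
               paths[2L], sep = "\t")
        fwrite(trajectory_distance_profile(traj), paths[3L], sep = "\t")
        list(tally = c(frames = n_frames(traj), atoms = nrow(traj$atoms)))
      })
  }, error = function(e) { cleanup(); stop(e) })
  log <- list(tool = "shmgrammar",
              version = as.character(utils::packageVersion("shmgrammar")),
              subcommand = config$subcommand, seed = config$seed,
              config_hash = config_hash(config),
              config = unclass(config), tally = as.list(res$tally))
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(list(artifacts = c(artifacts, log_path), log = log))
}

#' Command-line interface
#'
#' `shm <subcommand> [options]`, wrapped by the `exec/shm` script.
#' Every threshold flag defaults to its published value and the help
#' text states the processing-chain provenance of each. Exit status:
#' 0 ok, 1 data error, 2 configuration error.
#'
#' @param argv Character vector of command-line arguments
#'   (subcommand first).
#' @return Integer exit status, invisibly.
#' @export
shm_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: shm <simulate|repertoire|mutpe|traj> [options]"
  if (length(argv) == 0L || argv[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  sub <- argv[1L]
  if (!sub %in% c("simulate", "repertoire", "mutpe", "traj")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  opts <- list(
    optparse::make_option("--seed", type = "integer", default = 1L,
                          help = "global random seed [default %default]"),
    optparse::make_option("--out-dir", dest = "out_dir", default = ".",
                          help = "output directory [default %default]"),
    optparse::make_option("--input", default = NULL,
                          help = "primary input (TSV / FASTQ R1 / PDB)"),
    optparse::make_option("--input2", default = NULL,
                          help = "secondary input (FASTQ R2)"),
    optparse::make_option("--reference", default = NULL,
                          help = "amplicon reference FASTA"),
    optparse::make_option("--regions", default = NULL,
                          help = "region-map sidecar TSV"),
    optparse::make_option("--min-coverage", dest = "min_coverage",
                          type = "integer", default = 30L,
                          help = "context-group coverage floor; groups with coverage < this are excluded [default %default]"),
    optparse::make_option("--trim-min-q", dest = "trim_min_q",
                          type = "double", default = 25,
                          help = "mean quality floor for 5-nt sliding-window 3' trimming [default %default]"),
    optparse::make_option("--min-base-q", dest = "min_base_q",
                          type = "double", default = 30,
                          help = "pileup counts only bases with at least this quality [default %default]"),
    optparse::make_option("--depth", type = "integer", default = 1000L,
                          help = "simulated read-pair depth [default %default]"),
    optparse::make_option("--n-sequences", dest = "n_sequences",
                          type = "integer", default = 1000L,
                          help = "simulated repertoire size [default %default]")
  )
  parser <- optparse::OptionParser(option_list = opts, usage = usage)
  parsed <- tryCatch(
    optparse::parse_args(parser, args = argv[-1L]),
    error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(parsed)) return(invisible(2L))
  parsed$help <- NULL
  cfg <- tryCatch(do.call(run_config, c(list(subcommand = sub), parsed)),
                  error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(cfg)) return(invisible(2L))
  ok <- tryCatch({ run_pipeline(cfg); TRUE },
                 error = function(e) { message(conditionMessage(e)); FALSE })
  invisible(if (ok) 0L else 1L)
}
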