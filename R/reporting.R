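# Publication-style comparison tables and the command-line entry point.

RESULT_ROWS <- c("Total costs (Euros)", "Drug costs (Euros)",
                 "Other healthcare costs (Euros)", "Societal costs (Euros)",
                 "Total QALYs", "NHB", "Lifetime relapses",
                 "Time to EDSS 6 (years)", "Time in line 1 (years)")

cohort_column <- function(r) {
  c(r$costs$total, r$costs$drug, r$costs$other_healthcare, r$costs$societal,
    r$qalys, r$nhb, r$lifetime_relapses, r$time_to_edss6, r$time_in_line1)
}

#' Compare treatment sequences side by side
#'
#' Simulates each sequence with common random numbers (same cohort size
#' and seed) and tabulates the mean cost-effectiveness outcomes — costs by
#' category, QALYs, net health benefit, lifetime relapses, time to EDSS 6
#' and time in line 1. NHB is reported from unrounded internal values.
#' Optional combined columns average sequences that share a drug,
#' unweighted (each sequence equally likely).
#'
#' @param params A [model_parameters()] object.
#' @param seqs List of [sequence_spec()] objects.
#' @param n Cohort size per sequence.
#' @param seed Integer seed shared across sequences.
#' @param combine Optional named list mapping a combined-column label to
#'   the indices of `seqs` it averages.
#' @return An object of class `dmtseq_comparison` holding the cohort
#'   results and the formatted table.
#' @export
compare_sequences <- function(params, seqs, n = params$cohort$n_patients,
                              seed = 1L, combine = NULL) {
  if (inherits(seqs, "sequence_spec")) seqs <- list(seqs)
  results <- lapply(seqs, simulate_cohort, params = params, n = n, seed = seed)
  names(results) <- vapply(seqs, `[[`, "", "label")
  cols <- lapply(results, cohort_column)
  if (!is.null(combine)) {
    for (lbl in names(combine)) {
      comb <- combine_by_dmt(results[combine[[lbl]]], label = lbl)
      cols[[lbl]] <- cohort_column(comb)
    }
  }
  tab <- do.call(cbind, cols)
  rownames(tab) <- RESULT_ROWS
  structure(list(results = results, table = tab, n = n, seed = seed,
                 wtp = params$economics$wtp),
            class = "dmtseq_comparison")
}

#' @export
print.dmtseq_comparison <- function(x, ...) {
  cat(sprintf("Mean cost-effectiveness outcomes (n = %d per sequence, seed = %d)\n",
              x$n, x$seed))
  tab <- x$table
  euro <- grepl("Euros", rownames(tab))
  shown <- tab
  storage.mode(shown) <- "character"
  shown[euro, ] <- format(round(tab[euro, , drop = FALSE]), big.mark = ",",
                          trim = TRUE)
  shown[!euro, ] <- sprintf("%.2f", tab[!euro, , drop = FALSE])
  print(format(shown, justify = "right"), quote = FALSE)
  invisible(x)
}

#' Write a comparison table to a delimited file
#'
#' Euro rows are written as integer amounts, other rows at full precision.
#'
#' @param comparison A `dmtseq_comparison`.
#' @param path Output file.
#' @param dialect Decimal dialect.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(comparison, path,
                                dialect = c("point", "comma")) {
  dialect <- match.arg(dialect)
  tab <- comparison$table
  euro <- grepl("Euros", rownames(tab))
  tab[euro, ] <- round(tab[euro, ])
  df <- data.frame(outcome = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path,
                     sep = if (dialect == "comma") ";" else ",",
                     dec = if (dialect == "comma") "," else ".",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- command-line interface ------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: dmtseq <command> [options]",
    "",
    "commands:",
    "  synth           generate a synthetic parameter file (-o/--out)",
    "  compare         simulate sequences (--params, --seq ..., --n, --seed)",
    "  psa             probabilistic sensitivity analysis (--params, two --seq,",
    "                  --iterations, --cohort-n, --seed)",
    "  threshold-price cost-neutral price search (--params, --drug, --line,",
    "                  --ref-seq, --n, --seed, --tol)",
    "  threshold-rr    efficacy-parity relative-risk search (same options)",
    "  calibrate       calibration report for a parameter file",
    "",
    "common options: --params FILE --seq LABEL (repeatable, drugs joined by '-',",
    "  line-1b drug in brackets: INFB[GLA]-OCR-CLA-ALE) --n INT --seed INT",
    "  --iterations INT --cohort-n INT --tol REAL --drug NAME --line LABEL",
    "  --ref-seq LABEL --out PATH --dialect point|comma",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list(seq = character())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a %in% c("-h", "--help")) { opts$help <- TRUE; i <- i + 1L; next }
    if (!startsWith(a, "--") && !startsWith(a, "-"))
      stop("unexpected argument: ", a)
    key <- sub("^--?", "", a)
    if (i == length(argv)) stop("missing value for --", key)
    val <- argv[i + 1L]
    if (key == "seq") opts$seq <- c(opts$seq, val)
    else opts[[gsub("-", "_", key)]] <- val
    i <- i + 2L
  }
  opts
}

parse_seq_label <- function(label) {
  main <- strsplit(label, "-", fixed = TRUE)[[1]]
  line1b <- NULL
  if (grepl("\\[", main[1])) {
    line1b <- sub("^.*\\[(.*)\\]$", "\\1", main[1])
    main[1] <- sub("\\[.*\\]$", "", main[1])
  }
  sequence_spec(main, line1b = line1b)
}

cli_metadata <- function(out_dir, command, opts, seed) {
  meta <- list(command = command, seed = seed,
               options = opts[setdiff(names(opts), "seq")],
               sequences = opts$seq,
               package_version = as.character(utils::packageVersion("dmtseq")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(opts$params) && file.exists(opts$params))
    meta$params_md5 <- unname(tools::md5sum(opts$params))
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
}

#' Command-line entry point
#'
#' Dispatches `synth`, `compare`, `psa`, `threshold-price`, `threshold-rr`
#' and `calibrate` to the package functions, writing outputs and a
#' run-metadata file (command, seed, parameter-file digest, version) to
#' the output directory. A thin Rscript wrapper is installed at
#' `system.file("cli", "dmtseq.R", package = "dmtseq")`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 on success).
#' @export
dmtseq_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  res <- tryCatch({
    if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    command <- argv[1]
    opts <- parse_cli_args(argv[-1])
    if (isTRUE(opts$help)) { cat(cli_usage(), "\n"); return(invisible(0L)) }
    seed <- as.integer(opts$seed %||% 1L)
    out <- opts$out %||% "."
    dialect <- opts$dialect %||% "point"
    if (!command %in% "synth" && is.null(opts$params))
      stop("--params FILE is required for '", command, "'")
    load_params <- function() {
      if (!file.exists(opts$params))
        stop("parameter file not found: ", opts$params)
      load_model_parameters(opts$params, dialect = dialect)
    }
    need_seqs <- function(params, k) {
      if (length(opts$seq) < k)
        stop("'", command, "' needs ", k, " --seq argument(s); ",
             "sequence labels join drug names with '-', e.g. OCR-CLA-NAT-ALE")
      lapply(opts$seq, function(lbl) {
        s <- parse_seq_label(lbl)
        missing <- setdiff(c(s$lines, if (s$has_line1b) s$line1b),
                           names(params$dmts))
        if (length(missing))
          stop("unknown DMT(s) ", paste(missing, collapse = ", "),
               " in sequence ", lbl, "; valid names: ",
               paste(names(params$dmts), collapse = ", "))
        s
      })
    }

    switch(command,
      synth = {
        sc <- scenario_spec(seed = seed)
        params <- generate_synthetic_params(sc)
        path <- opts$out %||% "parameters.yaml"
        write_model_parameters(params, path, dialect = dialect)
        message("wrote ", path)
      },
      compare = {
        params <- load_params()
        seqs <- need_seqs(params, 1L)
        n <- as.integer(opts$n %||% params$cohort$n_patients)
        cmp <- compare_sequences(params, seqs, n = n, seed = seed)
        print(cmp)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_results_table(cmp, file.path(out, "comparison.csv"),
                            dialect = dialect)
        cli_metadata(out, command, opts, seed)
      },
      psa = {
        params <- load_params()
        seqs <- need_seqs(params, 2L)
        psa <- run_psa(seqs[[1]], seqs[[2]], params,
                       n_iterations = as.integer(opts$iterations %||% 500L),
                       cohort_n = as.integer(opts$cohort_n %||% 1000L),
                       seed = seed)
        print(psa)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        export_ce_plane(psa, file.path(out, "ce_plane.csv"),
                        plot_file = file.path(out, "ce_plane.png"),
                        dialect = dialect)
        cli_metadata(out, command, opts, seed)
      },
      `threshold-price` = ,
      `threshold-rr` = {
        params <- load_params()
        if (is.null(opts$drug)) stop("--drug NAME is required")
        line <- opts$line %||% "1a"
        n <- as.integer(opts$n %||% params$cohort$n_patients)
        tol <- as.numeric(opts$tol %||% 0.005)
        ref_seq <- parse_seq_label(
          opts$ref_seq %||% if (line == "1a") "OCR-CLA-NAT-ALE"
          else "INFB[GLA]-OCR-CLA-ALE")
        ref_nhb <- sequence_nhb(ref_seq, params, n = n, seed = seed)
        cand <- get_dmt(params, opts$drug)
        th <- if (command == "threshold-price")
          find_threshold_price(cand, line, ref_nhb, params, tol = tol,
                               seed = seed, cohort_n = n)
        else
          find_threshold_rr(cand, line, ref_nhb, params, tol = tol,
                            seed = seed, cohort_n = n)
        print(th)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(th$search_trace,
                           file.path(out, "threshold_trace.csv"),
                           sep = ",", row.names = FALSE, quote = FALSE)
        cli_metadata(out, command, opts, seed)
      },
      calibrate = {
        params <- load_params()
        n <- as.integer(opts$n %||% 2000L)
        print(calibration_report(params, n = n, seed = seed))
      },
      stop("unknown command: ", command, "\n", cli_usage())
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
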