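#' Summary statistics of a read set
#'
#' Length, quality and composition summaries plus the theoretical coverage
#' `total_bases / reference_length` (what the run would cover if every
#' base mapped). Standard deviations use the unbiased (n-1) estimator.
#' Note that run summary tables in this field sometimes label raw base
#' counts "Mbases"; this report always labels the column `total_bases`.
#'
#' @param reads Read tibble (`read_id`, `bases`, `quals`).
#' @param reference_length Reference genome length in bp (> 0).
#' @param track Optional [coverage_track()] supplying the realised
#'   coverage columns.
#' @return One-row tibble: `n_reads`, `total_bases`, `mean_len`, `sd_len`,
#'   `mean_qual`, `sd_qual`, `gc_percent`, `theoretical_coverage`,
#'   `actual_mean_coverage`, `breadth`, `empty`.
#' @export
summarize_readset <- function(reads, reference_length, track = NULL) {
  stopifnot(reference_length > 0)
  if (nrow(reads) == 0L) {
    return(tibble::tibble(
      n_reads = 0L, total_bases = 0, mean_len = 0, sd_len = 0,
      mean_qual = 0, sd_qual = 0, gc_percent = 0,
      theoretical_coverage = 0, actual_mean_coverage = NA_real_,
      breadth = NA_real_, empty = TRUE))
  }
  lens <- nchar(reads$bases)
  phred <- qual_to_phred(paste(reads$quals, collapse = ""))
  comp <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(reads$bases), letters = c("GC"), as.prob = FALSE)
  cov_mean <- NA_real_
  breadth <- NA_real_
  if (!is.null(track)) {
    cs <- coverage_summary(track)
    cov_mean <- cs$mean
    breadth <- cs$breadth
  }
  tibble::tibble(
    n_reads = nrow(reads),
    total_bases = sum(lens),
    mean_len = mean(lens),
    sd_len = stats::sd(lens),
    mean_qual = mean(phred),
    sd_qual = stats::sd(phred),
    gc_percent = 100 * sum(comp) / sum(lens),
    theoretical_coverage = sum(lens) / reference_length,
    actual_mean_coverage = cov_mean,
    breadth = breadth,
    empty = FALSE)
}

#' Fractions of reads mapped to the reference, to candidates, or unassigned
#'
#' Reads are partitioned into three disjoint classes: mapped to the
#' reference, mapped to a candidate (contaminant) genome, or unassigned.
#' A read present in both alignment sets counts for the reference (and is
#' reported in the `conflicts` attribute). Fractions are given on both a
#' per-read and a per-base basis, since the two can differ substantially.
#'
#' @param reads Read tibble.
#' @param alignments_ref Alignment tibble against the reference
#'   ([map_reads()] output; only `mapped` rows are used).
#' @param alignments_candidates Alignment tibble against candidate
#'   genomes, or `NULL`.
#' @return Tibble of class `assignment_fractions` with rows
#'   `basis = c("reads", "bases")` and columns `mapped_to_reference`,
#'   `mapped_to_candidates`, `unassigned` (each row sums to 1).
#' @export
assignment_fractions <- function(reads, alignments_ref,
                                 alignments_candidates = NULL) {
  mapped_ids <- function(a) {
    if (is.null(a) || nrow(a) == 0L) return(character(0))
    if ("mapped" %in% names(a)) a <- a[a$mapped, , drop = FALSE]
    unique(a$read_id)
  }
  ref_ids <- mapped_ids(alignments_ref)
  cand_ids <- mapped_ids(alignments_candidates)
  conflicts <- intersect(cand_ids, ref_ids)
  cand_ids <- setdiff(cand_ids, ref_ids)      # reference takes precedence
  cls <- dplyr::case_when(
    reads$read_id %in% ref_ids ~ "mapped_to_reference",
    reads$read_id %in% cand_ids ~ "mapped_to_candidates",
    TRUE ~ "unassigned")
  lens <- nchar(reads$bases)
  frac <- function(w) {
    tot <- sum(w)
    c(mapped_to_reference = sum(w[cls == "mapped_to_reference"]) / tot,
      mapped_to_candidates = sum(w[cls == "mapped_to_candidates"]) / tot,
      unassigned = sum(w[cls == "unassigned"]) / tot)
  }
  out <- dplyr::bind_rows(
    tibble::as_tibble_row(c(basis = "reads", frac(rep(1, nrow(reads))))),
    tibble::as_tibble_row(c(basis = "bases", frac(lens))))
  out <- dplyr::mutate(out, dplyr::across(-"basis", as.numeric))
  attr(out, "conflicts") <- conflicts
  class(out) <- c("assignment_fractions", class(out))
  out
}

#' Build a coverage track from simulation truth intervals
#'
#' Places each origin interval of the given truth classes on the named
#' genome; useful for ground-truth coverage, independent of mapping.
#'
#' @param truth Truth tibble from a simulator.
#' @param genome Target [genome()].
#' @param classes Truth classes to include.
#' @return A [coverage_track()].
#' @export
coverage_from_truth <- function(truth, genome,
                                classes = c("target", "chimera")) {
  t <- dplyr::filter(truth, .data$class %in% classes,
                     .data$genome_id == genome$id, !is.na(.data$start))
  coverage_track(tibble::tibble(ref_start = t$start, ref_end = t$end),
                 genome)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "dsmda_out",
    genome = list(length = 50000L, gc = 0.508, id = "reference"),
    contaminant = list(length = 50000L, gc = 0.435, id = "contaminant"),
    null_genome_length = 50000L,
    simulate = list(n_reads_ds = 3000L, n_reads_mda = 3000L,
                    read_len_mean = 230, read_len_sd = 137),
    reads = NULL,                       # list(ds = path, mda = path)
    qc = list(qual_window = 10, qual_threshold = 20, min_read_len = 40,
              adaptor_min_score = 24, entropy_k = 3, entropy_min = 0.5),
    adaptor3 = "CTGAGACTGCCAAGGCACACAGGGGATAGG",
    attach_prob = 0.5,
    mapping = list(word_size = 13, min_match_len = 30, min_identity = 0.9),
    compare = list(n_rep = 100, sample_size = 1000, n_perm = 199),
    attribution = list(k = 6, n_boot = 500, n_perm = 499),
    cluster_thresholds = c(0.99, 0.95, 0.9, 0.85, 0.8),
    cluster_max_reads = 300L
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML configuration merged over the package defaults; every omitted key
#' keeps its default. `seed` is mandatory in the file or the defaults, so
#' no run is silently nondeterministic.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] [%s] %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  writeLines(line, con)
  message(line)
}

#' Run the full DS-vs-MDA comparison pipeline
#'
#' Executes, in fixed order: genome setup, read simulation (or FASTQ
#' input), quality control, mapping against the reference, coverage
#' construction and statistical comparison, assignment-fraction
#' accounting, hexamer attribution of unassigned reads, and duplicate
#' clustering of the two read sets. Per-stage artifacts (FASTQ, truth
#' TSV, SAM, wiggle, BED, Newick, TSV tables) and a timestamped log are
#' written under `config$out_dir`; a run is fully reproducible from the
#' configuration and its seed.
#'
#' @param config A configuration list from [read_pipeline_config()], or a
#'   path to a YAML configuration file.
#' @return A list of class `pipeline_result`: `config`, `summary` (the
#'   combined DS/MDA table), `assignment` (per-method fractions),
#'   `comparison` (subsample CvM replicates), `attribution`,
#'   `cluster_curves`, `qc_reports`, and the output directory.
#' @export
run_pipeline <- function(config = read_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(!is.null(config$seed))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  run_stage <- function(stage, expr) {
    log_line(log_con, stage, "start")
    tryCatch(expr, error = function(e) {
      log_line(log_con, stage, paste("FAILED:", conditionMessage(e)))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed

  ## --- genomes ---------------------------------------------------------
  genomes <- run_stage("genomes", {
    ref <- generate_genome(config$genome$length, config$genome$gc,
                           seed = seed, id = config$genome$id)
    cont <- generate_genome(config$contaminant$length, config$contaminant$gc,
                            seed = seed + 1L, id = config$contaminant$id)
    null_g <- generate_null_genome(config$null_genome_length,
                                   seed = seed + 2L)
    write_genome_fasta(list(ref, cont, null_g),
                       file.path(config$out_dir, "genomes.fasta"))
    list(ref = ref, cont = cont, null = null_g)
  })

  ## --- reads -----------------------------------------------------------
  sim <- run_stage("reads", {
    if (!is.null(config$reads)) {
      log_line(log_con, "reads", "using user-supplied FASTQ input")
      list(ds = list(reads = read_fastq(config$reads$ds), truth = NULL),
           mda = list(reads = read_fastq(config$reads$mda), truth = NULL))
    } else {
      s <- config$simulate
      ds <- simulate_ds_reads(genomes$ref, s$n_reads_ds,
                              read_len_mean = s$read_len_mean,
                              read_len_sd = s$read_len_sd,
                              seed = seed + 10L, run_label = "DS")
      mda <- simulate_mda_reads(genomes$ref, s$n_reads_mda,
                                read_len_mean = s$read_len_mean,
                                read_len_sd = s$read_len_sd,
                                mda = mda_params(contaminant_genome = genomes$cont),
                                seed = seed + 11L, run_label = "MDA")
      ds$reads <- attach_adaptors(ds$reads, config$adaptor3, mid = "MID1",
                                  attach_prob = config$attach_prob,
                                  seed = seed + 12L)
      mda$reads <- attach_adaptors(mda$reads, config$adaptor3, mid = "MID2",
                                   attach_prob = config$attach_prob,
                                   seed = seed + 13L)
      write_fastq(ds$reads, file.path(config$out_dir, "ds_reads.fastq"))
      write_fastq(mda$reads, file.path(config$out_dir, "mda_reads.fastq"))
      write_truth_tsv(ds$truth, file.path(config$out_dir, "ds_truth.tsv"))
      write_truth_tsv(mda$truth, file.path(config$out_dir, "mda_truth.tsv"))
      list(ds = ds, mda = mda)
    }
  })

  ## --- qc --------------------------------------------------------------
  qc <- run_stage("qc", {
    cfg_qc <- do.call(qc_config, config$qc)
    out <- purrr::imap(sim, function(s, nm) {
      r <- run_qc(s$reads, cfg_qc, adaptor = config$adaptor3)
      write_qc_report(r$report,
                      file.path(config$out_dir, paste0(nm, "_qc_report.tsv")))
      r
    })
    log_line(log_con, "qc",
             sprintf("DS %d/%d, MDA %d/%d reads survive",
                     out$ds$report$surviving, out$ds$report$input,
                     out$mda$report$surviving, out$mda$report$input))
    out
  })

  ## --- mapping ---------------------------------------------------------
  mp <- config$mapping
  maps <- run_stage("mapping", {
    idx <- build_index(genomes$ref, mp$word_size)
    out <- purrr::imap(qc, function(q, nm) {
      al <- map_reads(idx, q$reads, mp$min_match_len, mp$min_identity)
      write_sam(al, idx, file.path(config$out_dir, paste0(nm, ".sam")))
      al
    })
    log_line(log_con, "mapping",
             sprintf("DS %d, MDA %d reads mapped to reference",
                     sum(out$ds$mapped), sum(out$mda$mapped)))
    out
  })

  ## --- coverage + comparison ------------------------------------------
  tracks <- run_stage("coverage", {
    out <- purrr::imap(maps, function(a, nm) {
      tr <- coverage_track(a, genomes$ref)
      write_wiggle(tr, file.path(config$out_dir, paste0(nm, "_coverage.wig")))
      write_covered_bed(tr, file.path(config$out_dir,
                                      paste0(nm, "_covered.bed")))
      tr
    })
    out
  })
  comparison <- run_stage("comparison", {
    cc <- config$compare
    cmp <- subsample_compare(tracks$ds, tracks$mda, n_rep = cc$n_rep,
                             sample_size = cc$sample_size,
                             seed = seed + 20L, n_perm = cc$n_perm)
    write_comparison_tsv(cmp, file.path(config$out_dir,
                                        "coverage_comparison.tsv"))
    log_line(log_con, "comparison",
             sprintf("median subsample CvM p = %.4g", attr(cmp, "median_p")))
    cmp
  })

  ## --- assignment + attribution ---------------------------------------
  cont_idx <- run_stage("candidate_index", {
    build_index(genomes$cont, mp$word_size)
  })
  assignment <- run_stage("assignment", {
    out <- purrr::imap_dfr(qc, function(q, nm) {
      un <- q$reads[!maps[[nm]]$mapped[match(q$reads$read_id,
                                             maps[[nm]]$read_id)], ,
                    drop = FALSE]
      cand_al <- if (nrow(un) > 0L) {
        map_reads(cont_idx, un, mp$min_match_len, mp$min_identity)
      } else NULL
      dplyr::mutate(assignment_fractions(q$reads, maps[[nm]], cand_al),
                    method = toupper(nm), .before = 1L)
    })
    readr::write_tsv(out, file.path(config$out_dir,
                                    "assignment_fractions.tsv"))
    out
  })
  attribution <- run_stage("attribution", {
    at <- config$attribution
    un_mda <- qc$mda$reads[!maps$mda$mapped[match(qc$mda$reads$read_id,
                                                  maps$mda$read_id)], ,
                           drop = FALSE]
    if (nrow(un_mda) == 0L) {
      log_line(log_con, "attribution", "no unassigned MDA reads; skipped")
      NULL
    } else {
      rep <- attribute_unassigned(un_mda,
                                  list(genomes$ref, genomes$cont),
                                  genomes$null, k = at$k,
                                  n_boot = at$n_boot, n_perm = at$n_perm,
                                  seed = seed + 30L)
      readr::write_tsv(rep$comparisons,
                       file.path(config$out_dir, "attribution.tsv"))
      if (!is.null(rep$clustering)) {
        write_newick(rep$clustering,
                     file.path(config$out_dir, "attribution.nwk"))
      }
      log_line(log_con, "attribution",
               sprintf("best candidate %s (support %s)", rep$best_candidate,
                       format(rep$best_support)))
      rep
    }
  })

  ## --- duplicate clustering -------------------------------------------
  curves <- run_stage("dedup", {
    out <- purrr::imap_dfr(qc, function(q, nm) {
      r <- q$reads
      if (nrow(r) > config$cluster_max_reads) {
        keep <- withr::with_seed(seed + 40L, {
          sample.int(nrow(r), config$cluster_max_reads)
        })
        r <- r[sort(keep), , drop = FALSE]
      }
      dplyr::mutate(cluster_curve(r, config$cluster_thresholds),
                    method = toupper(nm), .before = 1L)
    })
    readr::write_tsv(out, file.path(config$out_dir, "cluster_curves.tsv"))
    out
  })

  ## --- summary ---------------------------------------------------------
  summary <- run_stage("summary", {
    ref_len <- nchar(genomes$ref$sequence)
    out <- purrr::imap_dfr(qc, function(q, nm) {
      dplyr::mutate(summarize_readset(q$reads, ref_len,
                                      track = tracks[[nm]]),
                    method = toupper(nm), .before = 1L)
    })
    readr::write_tsv(out, file.path(config$out_dir, "summary.tsv"))
    out
  })
  log_line(log_con, "done", sprintf("artifacts in %s", config$out_dir))

  structure(list(config = config, summary = summary,
                 assignment = assignment, comparison = comparison,
                 attribution = attribution, cluster_curves = curves,
                 qc_reports = purrr::map_dfr(qc, "report"),
                 tracks = tracks, out_dir = config$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n\nSummary:\n")
  print(x$summary)
  cat("\nAssignment fractions:\n")
  print(x$assignment)
  cat(sprintf("\nMedian subsample CvM p: %.4g\n",
              attr(x$comparison, "median_p")))
  invisible(x)
}
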