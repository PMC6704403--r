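#' Run the full lncRNA discovery pipeline
#'
#' Orchestrates featurize -> classify -> genomic filter -> SPM -> preference
#' groups over file inputs, writing `scores.tsv`, `filter_report.tsv`,
#' `filter_summary.json`, `spm.tsv`, `groups.tsv` and a provenance record
#' `run.json` into `outdir`. The provenance record carries the resolved
#' configuration (every threshold and extension in force), input file
#' digests, per-stage record counts and output digests; it contains no
#' timestamps, so re-running with identical inputs and a fixed seed in
#' single-threaded mode reproduces every output byte.
#'
#' @param config A named list (or path to a flat YAML file mirroring the
#'   list) with entries:
#'   \describe{
#'     \item{candidates_fasta}{candidate transcript sequences (FASTA).}
#'     \item{candidates_gtf}{candidate transcript models (GTF).}
#'     \item{reference_gtf}{reference annotation (GTF); optional.}
#'     \item{model_file}{a saved classifier; alternatively supply
#'       `coding_fasta` + `noncoding_fasta` training corpora.}
#'     \item{expression_tsv, tissues_tsv}{abundance matrix and sample-to-
#'       tissue map; optional (skips the specificity stage).}
#'     \item{outdir}{output directory (created).}
#'     \item{seed, threshold, min_len, ext5, ext3, organ_a, organ_b,
#'       c_single, c_joint, n_rounds, eta, max_depth, nthread}{tuning knobs
#'       with the package defaults.}
#'   }
#' @return An object of class `pipeline_run` (the contents of `run.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L, threshold = 0.5, min_len = 200, ext5 = 160, ext3 = 792,
    organ_a = "VNO", organ_b = "MOE", c_single = 0.9, c_joint = 0.55,
    n_rounds = 500L, eta = 0.1, max_depth = 6L, nthread = 1L
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$outdir)) stop("config must name an outdir")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  # --- stage: inputs -------------------------------------------------------
  seqs <- stage("read_candidates", read_transcript_fasta(cfg$candidates_fasta))
  candidates <- NULL
  if (!is.null(cfg$candidates_gtf)) {
    candidates <- stage("parse_candidates_gtf", parse_gtf(cfg$candidates_gtf))
  }
  annotation <- NULL
  if (!is.null(cfg$reference_gtf)) {
    annotation <- stage("parse_reference_gtf", parse_gtf(cfg$reference_gtf))
  }

  # --- stage: model --------------------------------------------------------
  model <- stage("model", {
    if (!is.null(cfg$model_file)) {
      load_classifier(cfg$model_file)
    } else {
      coding <- read_transcript_fasta(cfg$coding_fasta)
      noncoding <- read_transcript_fasta(cfg$noncoding_fasta)
      ht <- train_hexamer_table(coding, noncoding)
      feats <- rbind(
        featurize_corpus(coding, ht),
        featurize_corpus(noncoding, ht)
      )
      corpus <- labeled_corpus(
        rownames(feats), feats,
        rep(c("coding", "lncRNA"), c(length(coding), length(noncoding)))
      )
      train_classifier(corpus,
        n_rounds = cfg$n_rounds, eta = cfg$eta,
        max_depth = cfg$max_depth, seed = cfg$seed,
        nthread = cfg$nthread, threshold = cfg$threshold,
        hexamer_table = ht
      )
    }
  })
  if (is.null(model$hexamer_table)) {
    stop("model carries no hexamer table; cannot featurize candidates")
  }

  # --- stage: classify -----------------------------------------------------
  scores <- stage("classify", {
    feats <- featurize_corpus(seqs, model$hexamer_table)
    predict_score(model, feats)
  })
  scores_path <- file.path(cfg$outdir, "scores.tsv")
  utils::write.table(
    data.frame(
      transcript_id = names(scores),
      score = scores,
      label = ifelse(scores >= cfg$threshold, "lncRNA", "coding")
    ),
    scores_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  # --- stage: genomic filter ----------------------------------------------
  if (is.null(candidates)) {
    report <- structure(
      list(
        candidates = data.frame(
          id = character(0), outcome = character(0), reason = character(0),
          overlap_fraction = numeric(0), stringsAsFactors = FALSE
        ),
        stage_counts = c(input = 0L, long = 0L, classified = 0L, clean = 0L)
      ),
      class = "filter_report"
    )
    kept <- character(0)
  } else {
    report <- stage("filter", filter_candidates(
      candidates, annotation, scores,
      threshold = cfg$threshold, min_len = cfg$min_len,
      ext5 = cfg$ext5, ext3 = cfg$ext3
    ))
    kept <- report$candidates$id[report$candidates$outcome == "kept"]
  }
  write_filter_report(
    report,
    file.path(cfg$outdir, "filter_report.tsv"),
    file.path(cfg$outdir, "filter_summary.json")
  )

  # --- stage: specificity --------------------------------------------------
  n_profiled <- 0L
  if (!is.null(cfg$expression_tsv)) {
    prof <- stage("specificity", {
      em <- read_expression_tsv(cfg$expression_tsv, cfg$tissues_tsv)
      specificity_profile(em,
        organ_a = cfg$organ_a, organ_b = cfg$organ_b,
        c_single = cfg$c_single, c_joint = cfg$c_joint
      )
    })
    spm_cols <- grep("^spm_", names(prof), value = TRUE)
    utils::write.table(prof[, c("transcript_id", spm_cols)],
      file.path(cfg$outdir, "spm.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    groups <- prof[, c(
      "transcript_id", "preference", "abundance", "expression_group"
    )]
    groups$kept_candidate <- groups$transcript_id %in% kept
    utils::write.table(groups, file.path(cfg$outdir, "groups.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    n_profiled <- nrow(prof)
  }

  # --- provenance ----------------------------------------------------------
  inputs <- unlist(cfg[names(cfg) %in% c(
    "candidates_fasta", "candidates_gtf", "reference_gtf", "model_file",
    "coding_fasta", "noncoding_fasta", "expression_tsv", "tissues_tsv"
  )])
  outputs <- list.files(cfg$outdir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "run.json"]
  run <- structure(
    list(
      package_version = as.character(utils::packageVersion("lncsieve")),
      config = cfg,
      feature_registry = feature_names(),
      input_md5 = as.list(tools::md5sum(inputs)),
      stage_counts = as.list(c(
        n_sequences = length(seqs), report$stage_counts,
        n_profiled = n_profiled
      )),
      output_md5 = as.list(tools::md5sum(sort(outputs)))
    ),
    class = "pipeline_run"
  )
  jsonlite::write_json(unclass(run), file.path(cfg$outdir, "run.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(run)
}

#' Order-stable intersection of candidate id lists
#'
#' Exact set intersection, keeping the order of the first list; used e.g.
#' to combine adult-enriched transcripts with those enriched in
#' OMP-positive cells.
#'
#' @param set_a,set_b Character vectors of ids.
#' @return Ids present in both lists, ordered as in `set_a`.
#' @export
intersect_candidates <- function(set_a, set_b) {
  unique(set_a[set_a %in% set_b])
}
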