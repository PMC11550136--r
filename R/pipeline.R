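# End-to-end orchestration: train the generator, sample novel sequences,
# optionally train the predictor and score the samples, evaluate the
# samples against the training corpus, and write a manifest. One global
# seed fans out to per-stage seeds by fixed offsets so any stage can be
# re-run independently yet reproducibly.

#' Run the generate-and-score pipeline
#'
#' Executes train -> sample -> (predict) -> evaluate and writes all
#' artifacts into \code{out_dir}: \code{checkpoint/} (generator weights,
#' config, log), \code{samples.fa}, optionally \code{predictor.rds} and
#' \code{preds.tsv}, \code{evaluation.json}, and \code{manifest.json}.
#' A stage failure aborts with the stage name; artifacts of completed
#' stages are left intact.
#'
#' @param sequences training corpus: character vector of equal-length
#'   sequences, or a FASTA path.
#' @param out_dir output directory (created if needed).
#' @param expression optional numeric labels (one per training sequence);
#'   enables the predictor stage.
#' @param n_samples number of sequences to generate (default 1000).
#' @param seed global seed; stage seeds are \code{seed + 1..4}.
#' @param top_k optional: also write \code{top_k.fa} with the highest
#'   predicted sequences (requires \code{expression}).
#' @param mdm_args list of extra arguments to [mdm()].
#' @param predictor_args list of extra arguments to [expr_cnn()].
#' @return invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(sequences, out_dir, expression = NULL,
                         n_samples = 1000, seed = 0, top_k = NULL,
                         mdm_args = list(), predictor_args = list()) {
  if (length(sequences) == 1 && file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  stopifnot(is.character(sequences), length(sequences) >= 2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  fit <- stage("train", do.call(mdm, c(list(x = unname(sequences),
                                            seed = seed + 1), mdm_args)))
  mdm_save(fit, file.path(out_dir, "checkpoint"))

  samples <- stage("sample", simulate(fit, nsim = n_samples, seed = seed + 2))
  write_fasta(stats::setNames(samples, sprintf("sample_%d", seq_along(samples))),
              file.path(out_dir, "samples.fa"))

  preds <- NULL
  predictor <- NULL
  if (!is.null(expression)) {
    predictor <- stage("predictor",
      do.call(expr_cnn, c(list(x = unname(sequences), y = expression,
                               seed = seed + 3), predictor_args)))
    saveRDS(predictor, file.path(out_dir, "predictor.rds"))
    preds <- stage("predict", data.frame(
      sequence_id = sprintf("sample_%d", seq_along(samples)),
      sequence = samples,
      prediction = predict(predictor, samples)))
    utils::write.table(preds, file.path(out_dir, "preds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(top_k)) {
      top <- select_top(preds, top_k)
      write_fasta(stats::setNames(top$sequence, top$sequence_id),
                  file.path(out_dir, "top_k.fa"))
    }
  }

  evalrep <- stage("evaluate", list(
    n_samples = length(samples),
    gc_js = gc_js_divergence(samples, sequences, seed = seed + 4),
    kmer_pearson = kmer_pearson(samples, sequences,
                                k = min(6, min(nchar(sequences)))),
    diversity = min_edit_diversity(samples,
                                   subsample = min(2000L, length(samples))),
    polyat = polyAT_fraction(samples),
    mean_gc = mean(gc_content(samples))))
  jsonlite::write_json(evalrep, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stage_seeds = list(train = seed + 1, sample = seed + 2,
                       predictor = seed + 3, evaluate = seed + 4),
    n_training_sequences = length(sequences),
    n_samples = n_samples,
    mdm_config = fit$config,
    predictor_config = if (is.null(predictor)) NULL else predictor$config,
    versions = list(promdiff = as.character(utils::packageVersion("promdiff")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(mdm = fit, samples = samples, predictor = predictor,
                 preds = preds, evaluation = evalrep, out_dir = out_dir))
}

#' Select the top-k sequences by predicted expression
#'
#' Sorts predictions in decreasing order (ties broken by lexicographic
#' sequence order, so the selection is stable) and returns the first k.
#'
#' @param preds data.frame with columns \code{sequence} and
#'   \code{prediction} (and optionally \code{sequence_id}), or a path to
#'   a TSV with those columns.
#' @param k number of sequences to keep (1 <= k <= nrow).
#' @return data.frame of the k selected rows, best first.
#' @export
select_top <- function(preds, k) {
  if (is.character(preds) && length(preds) == 1) {
    preds <- utils::read.table(preds, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(preds),
            all(c("sequence", "prediction") %in% names(preds)))
  if (k <= 0) stop("k must be positive")
  if (k > nrow(preds)) stop("k exceeds the number of predictions")
  ord <- order(-preds$prediction, preds$sequence)
  out <- preds[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
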