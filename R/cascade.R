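#' Train the three cascade classifiers on synthetic data
#'
#' Fits the stage-1 (VF vs non-VF), stage-2 (AF vs non-AF) and stage-3 (PVC
#' vs normal beat) classifiers on balanced [synth_dataset()] feature
#' tables. The result plugs straight into [run_cascade()].
#'
#' @param n_per_class Training samples per class and stage.
#' @param kind Classifier family for all stages: `"bdt"` or `"svm"`.
#' @param seed Integer seed (stage datasets use `seed`, `seed + 1`,
#'   `seed + 2`).
#' @param noise_sd Generator noise level.
#' @return A named list of three `ecg_classifier` objects (`vf`, `af`,
#'   `pvc`) of class `ecg_cascade_models`.
#' @export
train_cascade <- function(n_per_class = 100L, kind = c("bdt", "svm"),
                          seed = 1L, noise_sd = 0.02) {
  kind <- match.arg(kind)
  models <- list(
    vf = fit_classifier(synth_dataset("vf", n_per_class, seed = seed,
                                      noise_sd = noise_sd), kind),
    af = fit_classifier(synth_dataset("af", n_per_class, seed = seed + 1L,
                                      noise_sd = noise_sd), kind),
    pvc = fit_classifier(synth_dataset("pvc", n_per_class, seed = seed + 2L,
                                       noise_sd = noise_sd), kind)
  )
  structure(models, class = "ecg_cascade_models")
}

#' @export
print.ecg_cascade_models <- function(x, ...) {
  cat("<ecg_cascade_models>\n")
  for (nm in names(x)) {
    cat(sprintf(" stage %-3s: ", nm)); print(x[[nm]])
  }
  invisible(x)
}

#' Run the four-stage arrhythmia cascade on a recording
#'
#' The full discrimination pipeline, one decision per 8 s segment with
#' strict stage ordering:
#' 1. preprocessing (resample to 300 Hz, 0.4-30 Hz band-pass, overlapping
#'    normalized segmentation);
#' 2. stage 1 - the six-feature VF classifier; a VF call stops the cascade
#'    for that segment;
#' 3. stage 2 - R peaks are detected and the RR-feature AF classifier runs;
#'    an AF call stops here. Segments with fewer than `min_beats` peaks are
#'    flagged unclassifiable; segments whose cleaned RR series is too short
#'    for the AF features (heavy ectopic exclusion) are treated as non-AF
#'    and passed on, since beat-driven irregularity is stage 3's job;
#' 4. stages 3-4 - every beat is classified PVC/normal and the 0/1 label
#'    vector is mapped to an episode code (the element of the vector of
#'    episode type, VET).
#'
#' @param record An [ecg_record()] at any sampling rate (>= 8 s).
#' @param models Trained classifiers from [train_cascade()] (or a
#'   compatible named list with elements `vf`, `af`, `pvc`).
#' @param seg_len_s,overlap_s Segmentation parameters.
#' @param min_beats Minimum detected R peaks for stages 2-4.
#' @return A tibble with one row per segment: `segment_id`, `start_s`,
#'   `stage1` (`"vf"`/`"non-vf"`), `stage2` (`"af"`/`"non-af"` or `NA`),
#'   `n_beats`, `episode_code` (1-7 or `NA`), `episode` (name), and `label`
#'   (the final call: `"VF"`, `"AF"`, an episode name, or
#'   `"unclassifiable"`).
#' @examples
#' \donttest{
#' models <- train_cascade(n_per_class = 30, seed = 1)
#' rec <- synth_ecg("bg", duration_s = 16, seed = 5)$record
#' run_cascade(rec, models)
#' }
#' @export
run_cascade <- function(record, models, seg_len_s = 8, overlap_s = 3,
                        min_beats = 5L) {
  stopifnot(inherits(record, "ecg_record"))
  if (!all(c("vf", "af", "pvc") %in% names(models))) {
    ecg_abort("`models` must contain stages `vf`, `af` and `pvc`.", "config")
  }
  segs <- preprocess_ecg(record, seg_len_s = seg_len_s, overlap_s = overlap_s)
  fs <- segs$fs[[1]]
  stage1_feat <- vf_features(segs)
  stage1 <- predict(models$vf, stage1_feat)
  af_feat <- af_features(segs, min_beats = min_beats)

  rows <- map(seq_len(nrow(segs)), function(i) {
    out <- tibble(segment_id = segs$segment_id[[i]],
                  start_s = segs$start_s[[i]],
                  stage1 = "non-vf", stage2 = NA_character_,
                  n_beats = af_feat$n_beats[[i]],
                  episode_code = NA_integer_, episode = NA_character_,
                  label = NA_character_)
    if (stage1[i] == "vf") {
      out$stage1 <- "vf"; out$label <- "VF"
      return(out)
    }
    if (af_feat$n_beats[[i]] < min_beats) {
      out$label <- "unclassifiable"
      return(out)
    }
    if (af_feat$usable[[i]]) {
      af_call <- predict(models$af,
                         af_feat[i, c("se_rr", "tpr", "rmssd_n")])
      if (af_call == "af") {
        out$stage2 <- "af"; out$label <- "AF"
        return(out)
      }
    }
    out$stage2 <- "non-af"
    x <- segs$samples[[i]]
    b <- cut_beats(x, detect_r_peaks(x, fs = fs))
    if (length(b) == 0L) {
      out$label <- "unclassifiable"
      return(out)
    }
    feats <- pvc_features(lapply(b, identity), fs = fs)
    labels <- as.integer(predict(models$pvc,
                                 feats[, c("lmmd", "msa", "wse", "kurt")]) == "pvc")
    out$episode_code <- classify_episode(labels)
    out$episode <- episode_name(out$episode_code)
    out$label <- out$episode
    out
  })
  bind_rows(rows)
}
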