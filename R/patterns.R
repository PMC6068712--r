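EPISODE_NAMES <- c("NSR", "couplet", "triplet", "VT",
                   "bigeminy", "trigeminy", "quadrigeminy")

# accept integer vectors or compact "10010010" strings
as_label_vector <- function(labels) {
  if (is.character(labels) && length(labels) == 1L) {
    labels <- as.integer(strsplit(labels, "")[[1]])
  }
  labels <- as.integer(labels)
  if (length(labels) == 0L) ecg_abort("label vector must be non-empty.", "config")
  if (!all(labels %in% c(0L, 1L))) {
    ecg_abort("label vector must contain only 0 (non-PVC) and 1 (PVC).", "config")
  }
  labels
}

#' Longest run of consecutive PVC beats (NCPVC)
#'
#' @param labels 0/1 per-beat PVC labels: an integer vector or a compact
#'   string such as `"11011011"`.
#' @return Integer: length of the longest run of 1s (0 if no PVC).
#' @examples
#' max_consecutive_pvc("11011011")  # 2
#' @export
max_consecutive_pvc <- function(labels) {
  labels <- as_label_vector(labels)
  rl <- rle(labels)
  runs <- rl$lengths[rl$values == 1L]
  if (length(runs)) as.integer(max(runs)) else 0L
}

#' Classify the PVC pattern of one segment into an episode code
#'
#' Decision rule over the per-beat 0/1 label vector. First the longest
#' consecutive-PVC run (NCPVC) decides: 0 PVCs -> NSR (1); a run of >= 4 ->
#' VT (4); 3 -> triplet (3); 2 -> couplet (2). For isolated PVCs (NCPVC =
#' 1) the spacing between successive PVC positions decides: a modal spacing
#' of 2, 3 or 4 beats maps to bigeminy (5), trigeminy (6) or quadrigeminy
#' (7) respectively. Tied modal spacings resolve to the smaller spacing
#' (bigeminy before trigeminy before quadrigeminy). A single isolated PVC,
#' or spacings outside 2-4, fall back to NSR.
#'
#' @inheritParams max_consecutive_pvc
#' @return Integer episode code in 1..7; see [episode_name()].
#' @examples
#' classify_episode("10101010")  # 5, bigeminy
#' classify_episode("11101110")  # 3, triplet
#' @export
classify_episode <- function(labels) {
  labels <- as_label_vector(labels)
  nc <- max_consecutive_pvc(labels)
  if (nc == 0L) return(1L)
  if (nc >= 4L) return(4L)
  if (nc == 3L) return(3L)
  if (nc == 2L) return(2L)
  pos <- which(labels == 1L)
  if (length(pos) < 2L) return(1L)
  gaps <- diff(pos)
  tab <- table(gaps)
  modal <- as.integer(names(tab)[which.max(tab)])  # ties: smallest spacing
  switch(as.character(modal), "2" = 5L, "3" = 6L, "4" = 7L, 1L)
}

#' Episode-code names
#'
#' @param code Integer vector of episode codes in 1..7.
#' @return Character vector: NSR, couplet, triplet, VT, bigeminy,
#'   trigeminy, quadrigeminy.
#' @export
episode_name <- function(code) {
  if (any(!code %in% 1:7)) ecg_abort("episode codes must be in 1..7.", "config")
  EPISODE_NAMES[code]
}

#' Build the vector of episode type (VET) for a recording
#'
#' Applies [classify_episode()] to the per-beat label vector of every
#' segment, giving one episode code per 8 s window of the recording.
#'
#' @param per_segment_labels List of 0/1 label vectors (or compact strings),
#'   one per segment, in order.
#' @return A tibble with columns `segment` (index), `code` (1..7) and
#'   `episode` (name).
#' @examples
#' build_vet(list("10101010", "11011011"))  # bigeminy then couplet
#' @export
build_vet <- function(per_segment_labels) {
  if (length(per_segment_labels) == 0L) {
    ecg_abort("need at least one segment label vector.", "config")
  }
  codes <- map_int(per_segment_labels, classify_episode)
  tibble(segment = seq_along(codes), code = codes, episode = episode_name(codes))
}
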