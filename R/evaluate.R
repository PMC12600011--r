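#' Match recovered inputs to planted ground truth
#'
#' Greedy one-to-one matching of recovered input centroids to planted input
#' positions (nearest first, within `max_dist_nm`), with recall, precision,
#' class accuracy and eye-assignment accuracy. Dominant-eye assignments are
#' scored against the planted CTB label (eye-A inputs missing tracer by
#' chance are correctly non-dominant).
#'
#' @param inputs recovered inputs table from [classify_inputs()].
#' @param scene the [generate_scene()] ground truth.
#' @param max_dist_nm maximum centroid-to-centroid match distance.
#' @return list: `matches` data.frame, `recall`, `precision`,
#'   `class_accuracy`, `eye_accuracy`, `az_count_accuracy`.
#' @export
match_ground_truth <- function(inputs, scene, max_dist_nm = 500) {
  gt <- scene$inputs
  if (nrow(inputs) == 0 || nrow(gt) == 0)
    return(list(matches = data.frame(), recall = 0, precision = 0,
                class_accuracy = NA, eye_accuracy = NA,
                az_count_accuracy = NA))
  d <- matrix(NA_real_, nrow(inputs), nrow(gt))
  for (i in seq_len(nrow(inputs)))
    d[i, ] <- sqrt((gt$x - inputs$cx[i])^2 + (gt$y - inputs$cy[i])^2 +
                     (gt$z - inputs$cz[i])^2)
  pairs <- which(d <= max_dist_nm, arr.ind = TRUE)
  if (nrow(pairs)) pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_r <- used_g <- logical(0)
  mr <- mg <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (i %in% mr || j %in% mg) next
    mr <- c(mr, i); mg <- c(mg, j)
  }
  matches <- data.frame(
    input_id = inputs$input_id[mr],
    gt_id = gt$id[mg],
    dist_nm = d[cbind(mr, mg)],
    true_class = gt$class[mg],
    recovered_class = inputs$input_class[mr],
    true_az_count = gt$az_count[mg],
    recovered_az_count = inputs$az_count[mr],
    true_ctb = gt$ctb[mg],
    recovered_eye = inputs$eye[mr],
    true_volume_um3 = gt$vesicle_volume[mg],
    recovered_volume_um3 = inputs$vesicle_volume_um3[mr])
  list(matches = matches,
       recall = nrow(matches) / nrow(gt),
       precision = nrow(matches) / nrow(inputs),
       class_accuracy = mean(matches$true_class == matches$recovered_class),
       eye_accuracy = mean((matches$recovered_eye == "dominant") ==
                             matches$true_ctb),
       az_count_accuracy = mean(matches$true_az_count ==
                                  matches$recovered_az_count))
}
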