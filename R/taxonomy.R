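#' Motor ability taxonomies
#'
#' Category sets for the three per-second annotation tracks used throughout
#' the package: seven postures (five main plus two intermediate side-lying
#' categories), nine movement qualities (four graded levels plus five
#' intermediate types), and five carrying states describing contact with an
#' adult. Fused variants merge left/right categories for recording-level
#' distribution features.
#'
#' @return Character vector of category names.
#' @name taxonomy
NULL

#' @rdname taxonomy
#' @export
posture_classes <- function() {
  c("supine", "prone", "side_left", "side_right",
    "crawl_posture", "sitting", "standing")
}

#' @rdname taxonomy
#' @export
movement_classes <- function() {
  c("still", "proto", "elementary", "fluent",
    "pivot_left", "pivot_right", "roll_left", "roll_right", "transition")
}

#' @rdname taxonomy
#' @export
carrying_classes <- function() {
  c("independent", "passive_support", "active_support",
    "passive_carry", "active_carry")
}

#' @rdname taxonomy
#' @export
fused_posture_classes <- function() {
  c("supine", "prone", "side", "crawl_posture", "sitting", "standing")
}

#' @rdname taxonomy
#' @export
fused_movement_classes <- function() {
  c("still", "proto", "elementary", "fluent", "pivot", "roll", "transition")
}

#' @rdname taxonomy
#' @export
sensor_ids <- function() {
  c("left_arm", "right_arm", "left_leg", "right_leg")
}

#' Fuse left/right categories of a label vector
#'
#' Maps `side_left`/`side_right` to `side` and `pivot_*`/`roll_*` to
#' `pivot`/`roll`; other labels pass through.
#'
#' @param labels character vector of posture or movement labels.
#' @return character vector of fused labels.
#' @export
fuse_lr <- function(labels) {
  map <- c(side_left = "side", side_right = "side",
           pivot_left = "pivot", pivot_right = "pivot",
           roll_left = "roll", roll_right = "roll")
  hit <- labels %in% names(map)
  labels[hit] <- map[labels[hit]]
  labels
}

#' Class priority orders used for deterministic tie-breaking
#'
#' When plurality-time frame labelling or majority voting ties, the label
#' earlier in the track's priority order wins. The orders put the main
#' categories before the intermediate ones.
#'
#' @param track one of `"posture"`, `"movement"`, `"carrying"`.
#' @return character vector: the track's classes in priority order.
#' @export
track_priority <- function(track) {
  switch(match.arg(track, c("posture", "movement", "carrying")),
    posture = c("supine", "prone", "sitting", "standing", "crawl_posture",
                "side_left", "side_right"),
    movement = c("still", "proto", "elementary", "fluent", "transition",
                 "pivot_left", "pivot_right", "roll_left", "roll_right"),
    carrying = c("independent", "passive_support", "active_support",
                 "passive_carry", "active_carry"))
}

track_classes <- function(track) {
  switch(match.arg(track, c("posture", "movement", "carrying")),
    posture = posture_classes(),
    movement = movement_classes(),
    carrying = carrying_classes())
}
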