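#' Canonical 10-channel lower-extremity montage
#'
#' The pipeline records five muscles per leg: tibialis anterior (TA),
#' peroneus longus (PL), rectus femoris (RF), gastrocnemius medialis (GM)
#' and semitendinosus (ST), on the right (`r`) and left (`l`) side. All
#' downstream math indexes this fixed order; one canonical order removes
#' silent permutation bugs.
#'
#' @return Character vector of the 10 channel labels, right side first:
#'   `"TA_r"`, `"PL_r"`, `"RF_r"`, `"GM_r"`, `"ST_r"`, then the left side.
#' @export
#' @examples
#' canonical_channels()
canonical_channels <- function() {
  muscles <- c("TA", "PL", "RF", "GM", "ST")
  c(paste0(muscles, "_r"), paste0(muscles, "_l"))
}

#' @rdname canonical_channels
#' @export
montage_muscles <- function() c("TA", "PL", "RF", "GM", "ST")

#' Index map that mirrors the montage across the body midline
#'
#' Swaps the right-side and left-side blocks of the canonical channel
#' order, so that `values[mirror_index()]` re-expresses a left-leg task
#' in right-leg coordinates (ipsilateral onto ipsilateral).
#'
#' @return Integer vector of length 10.
#' @export
mirror_index <- function() c(6:10, 1:5)

#' Joints and task identifiers
#'
#' Tasks are single-joint reciprocal movements of the hip, knee, ankle and
#' subtalar joint (STJ), performed once per leg; a session therefore holds
#' 8 tasks. Tasks are identified by `"<joint>_<side>"` with the physical
#' side `r`/`l`; the less/more-affected view used by the validation
#' battery is derived per subject from an `affected_side` label.
#'
#' @return `montage_joints()`: the 4 joint names; `all_tasks()`: the 8
#'   task identifiers in the testing order (knee, ankle, STJ, hip; right
#'   leg then left leg).
#' @export
montage_joints <- function() c("hip", "knee", "ankle", "STJ")

#' @rdname montage_joints
#' @export
all_tasks <- function() {
  joints <- c("knee", "ankle", "STJ", "hip")  # testing order
  c(paste0(joints, "_r"), paste0(joints, "_l"))
}

#' Target agonist/antagonist muscle pair per joint
#'
#' Used by the co-activation / mirror-activity decomposition to define
#' which two recorded muscles are "on target" for a task: ankle
#' dorsi/plantarflexion uses TA and GM, knee extension/flexion RF and ST,
#' subtalar inversion/eversion PL and TA, hip flexion/extension RF and ST.
#' This mapping is an interpretive choice confined to the decomposition
#' report (the recorded montage does not include deep hip muscles).
#'
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`, `"STJ"`.
#' @return Character vector of two muscle codes.
#' @export
target_muscles <- function(joint) {
  joint <- match.arg(joint, montage_joints())
  switch(joint,
    ankle = c("TA", "GM"),
    knee  = c("RF", "ST"),
    STJ   = c("PL", "TA"),
    hip   = c("RF", "ST")
  )
}

#' Channel indices (canonical order) for the target pair of a task
#'
#' @param task Task identifier, e.g. `"ankle_r"`.
#' @return Integer vector of two indices into [canonical_channels()].
#' @export
target_channel_index <- function(task) {
  p <- parse_task(task)
  match(paste0(target_muscles(p$joint), "_", p$side), canonical_channels())
}

#' Split a task identifier into joint and side
#'
#' @param task Task identifier `"<joint>_<side>"`.
#' @return List with elements `joint` and `side`.
#' @export
parse_task <- function(task) {
  stopifnot(is.character(task), length(task) == 1L)
  m <- regmatches(task, regexec("^(hip|knee|ankle|STJ)_(r|l)$", task))[[1]]
  if (length(m) != 3L) {
    stop("invalid task identifier: '", task,
         "' (expected <joint>_<side> with joint in hip/knee/ankle/STJ)",
         call. = FALSE)
  }
  list(joint = m[2], side = m[3])
}

#' Channel indices of one body side
#'
#' @param side `"r"` or `"l"`.
#' @return Integer vector of 5 indices into the canonical order.
#' @export
side_channel_index <- function(side) {
  side <- match.arg(side, c("r", "l"))
  if (side == "r") 1:5 else 6:10
}
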