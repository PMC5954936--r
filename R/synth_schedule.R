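#' Motor-imagery task taxonomy
#'
#' The full task battery: 16 independent arm movements per upper extremity
#' (8 degrees of freedom x 2 directions), mirrored for the left and right
#' arm (32 arm tasks), plus one walking task — 33 imagery tasks in total.
#' Each arm task is classified by proximity (shoulder/elbow/forearm joints
#' are proximal, wrist/thumb/fingers distal) and by resulting motion
#' (rotational for the forearm and wrist rotations, linear otherwise).
#'
#' @return Data frame with columns `task_id`, `joint`, `direction`, `side`,
#'   and logical category columns.
#' @export
task_table <- function() {
  arm <- data.frame(
    joint = c(rep("Shoulder", 4), rep("Elbow", 2), rep("Forearm", 2),
              rep("Wrist", 4), rep("Thumb", 2), rep("Fingers", 2)),
    direction = c("Arm down", "Arm up", "Arm left", "Arm right",
                  "Forearm down", "Forearm up",
                  "External rotation", "Internal rotation",
                  "Hand down", "Hand up", "External rotation",
                  "Internal rotation",
                  "Open", "Close", "Open", "Close"),
    proximity = c(rep("Proximal", 8), rep("Distal", 8)),
    motion = c(rep("Linear", 6), rep("Rotational", 2),
               rep("Linear", 2), rep("Rotational", 2), rep("Linear", 4)),
    stringsAsFactors = FALSE)
  both <- rbind(cbind(arm, side = "left"), cbind(arm, side = "right"))
  both$task_id <- sprintf("%s_%s_%s",
                          tolower(substr(both$side, 1, 1)),
                          gsub(" ", "", tolower(both$joint)),
                          gsub(" ", "", tolower(both$direction)))
  walking <- data.frame(joint = "Walking", direction = "", side = "",
                        proximity = "", motion = "", task_id = "walking",
                        stringsAsFactors = FALSE)
  rbind(both[, c("task_id", "joint", "direction", "side", "proximity", "motion")],
        walking[, c("task_id", "joint", "direction", "side", "proximity", "motion")])
}

#' Map a task descriptor to its imagery categories
#'
#' Arm tasks always belong to Hands plus their laterality (Left/Right),
#' proximity (Proximal/Distal) and motion (Rotational/Linear) categories;
#' the walking task belongs only to Walking.
#'
#' @param joint One of Shoulder, Elbow, Forearm, Wrist, Thumb, Fingers, or
#'   Walking.
#' @param direction Movement direction as listed in [task_table()] (ignored
#'   for Walking).
#' @param side `"left"` or `"right"` arm (ignored for Walking).
#' @return Character vector of category labels.
#' @export
categorize_task <- function(joint, direction = NULL, side = NULL) {
  if (identical(joint, "Walking")) return("Walking")
  tab <- task_table()
  row <- tab[tab$joint == joint & tab$direction == direction &
               tab$side == side, ]
  if (nrow(row) != 1L)
    stop_invalid("unknown task descriptor: %s / %s / %s",
                 joint, direction %||% "", side %||% "")
  c("Hands",
    if (row$side == "left") "Left" else "Right",
    row$proximity, row$motion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Categories for a task id
#' @param task_id A `task_id` from [task_table()].
#' @return Character vector of category labels.
#' @export
task_categories <- function(task_id) {
  tab <- task_table()
  row <- tab[tab$task_id == task_id, ]
  if (nrow(row) != 1L) stop_invalid("unknown task_id '%s'", task_id)
  categorize_task(row$joint,
                  if (row$joint == "Walking") NULL else row$direction,
                  if (row$joint == "Walking") NULL else row$side)
}

#' Generate a randomized presentation schedule
#'
#' Every task is presented exactly `n_repetitions` times in a globally random
#' order, split into `n_parts` consecutive presentation blocks; within a
#' block, consecutive onsets are spaced by the video duration plus the rest
#' interval. The default geometry is 34 stimuli (32 arm tasks + walking +
#' oddball) x 9 repetitions over 3 parts with 5 s videos and 4 s rests.
#'
#' @param n_tasks Number of distinct stimuli.
#' @param n_repetitions Presentations per stimulus.
#' @param video_s Video duration in seconds.
#' @param rest_s Rest (black screen) duration in seconds.
#' @param n_parts Number of presentation blocks.
#' @param seed Integer seed for the presentation order.
#' @param task_ids Optional character ids (default `task01`, ...).
#' @return Object of class `experiment_schedule`: a data frame with columns
#'   `task_id`, `part`, `onset_s`, plus attributes `n_repetitions`,
#'   `video_s`, `rest_s`.
#' @export
generate_schedule <- function(n_tasks = 34, n_repetitions = 9, video_s = 5,
                              rest_s = 4, n_parts = 3, seed = 1,
                              task_ids = NULL) {
  n_tasks <- check_count(n_tasks, "n_tasks")
  n_repetitions <- check_count(n_repetitions, "n_repetitions")
  n_parts <- check_count(n_parts, "n_parts")
  stopifnot(video_s > 0, rest_s >= 0)
  if (is.null(task_ids)) task_ids <- sprintf("task%02d", seq_len(n_tasks))
  stopifnot(length(task_ids) == n_tasks)
  total <- n_tasks * n_repetitions
  order <- with_seed(seed, sample(rep(task_ids, n_repetitions)))
  part_sizes <- rep(total %/% n_parts, n_parts)
  extra <- total - sum(part_sizes)
  if (extra > 0) part_sizes[seq_len(extra)] <- part_sizes[seq_len(extra)] + 1L
  part <- rep(seq_len(n_parts), part_sizes)
  onset <- unlist(lapply(part_sizes, function(m) (seq_len(m) - 1) * (video_s + rest_s)))
  sched <- data.frame(task_id = order, part = part, onset_s = onset,
                      stringsAsFactors = FALSE)
  structure(sched, class = c("experiment_schedule", "data.frame"),
            n_repetitions = n_repetitions, video_s = video_s, rest_s = rest_s)
}
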