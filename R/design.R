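#' Factorial session design specification
#'
#' Describes one cursor-control session: which visibility conditions
#' exist, the four trial types, the visuomotor-rotation grid, the grid of
#' instructed approximate movement directions, and how often the full
#' trial-type-by-rotation set is repeated. The defaults reproduce the
#' study design this package targets: 4 trial types x 8 rotations
#' (-17.5 to +17.5 deg in steps of 5, mean 0) repeated 10 times = 320
#' trials per session, with 8 instructed directions from -56 to +56 deg
#' (step 16) relative to straight ahead, presented in 6 blocks.
#'
#' Angles live in two frames: rotations and instructed directions are
#' stored relative to straight ahead, while endpoint angles used
#' downstream lie on the semicircular stopper ring in \[0, 180\] degrees
#' with 90 = straight ahead (conversion is `+ 90`).
#'
#' @param conditions Character vector of visibility-condition labels.
#' @param trial_types Character vector drawn from `UniHand`, `UniCursor`,
#'   `BiHand`, `BiCursor`.
#' @param rotations_deg Numeric grid of visuomotor rotations (degrees).
#' @param directions_deg Numeric grid of instructed directions (degrees
#'   relative to straight ahead).
#' @param n_repetitions Number of repetitions of the full
#'   trial-type-by-rotation set per session.
#' @param n_blocks Number of presentation blocks (annotation only; no
#'   ordering constraint is tied to blocks).
#' @return An object of class `design_spec`.
#' @examples
#' spec <- design_spec()
#' rotation_grid_stats(spec)
#' @export
design_spec <- function(conditions = c("Dyn", "End", "DynEnd"),
                        trial_types = c("UniHand", "UniCursor",
                                        "BiHand", "BiCursor"),
                        rotations_deg = seq(-17.5, 17.5, by = 5),
                        directions_deg = seq(-56, 56, by = 16),
                        n_repetitions = 10L,
                        n_blocks = 6L) {
  stopifnot(
    length(conditions) >= 1, length(trial_types) >= 1,
    length(rotations_deg) >= 1, length(directions_deg) >= 1,
    n_repetitions >= 1, n_blocks >= 1
  )
  bad <- setdiff(trial_types, c("UniHand", "UniCursor", "BiHand", "BiCursor"))
  if (length(bad) > 0) {
    stop("Unknown trial types: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rotations_deg)) {
    stop("`rotations_deg` must be distinct values.", call. = FALSE)
  }
  structure(
    list(
      conditions = conditions,
      trial_types = trial_types,
      rotations_deg = rotations_deg,
      directions_deg = directions_deg,
      n_repetitions = as.integer(n_repetitions),
      n_blocks = as.integer(n_blocks)
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat("  conditions:  ", paste(x$conditions, collapse = ", "), "\n")
  cat("  trial types: ", paste(x$trial_types, collapse = ", "), "\n")
  cat("  rotations:   ", paste(x$rotations_deg, collapse = ", "), "deg\n")
  cat("  directions:  ", paste(x$directions_deg, collapse = ", "), "deg\n")
  cat("  repetitions: ", x$n_repetitions,
      " (", x$n_repetitions * length(x$trial_types) * length(x$rotations_deg),
      " trials/session in ", x$n_blocks, " blocks)\n", sep = "")
  invisible(x)
}

#' Summary statistics of the rotation grid
#'
#' @param spec A [design_spec()].
#' @return A list with `count` (number of distinct rotations) and
#'   `mean_deg` (their arithmetic mean). The default grid has 8 rotations
#'   with mean exactly 0.
#' @export
rotation_grid_stats <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  list(count = length(spec$rotations_deg), mean_deg = mean(spec$rotations_deg))
}

#' Build one semi-randomized session
#'
#' Produces the ordered trial list for a single session. Each repetition
#' set contains every (trial type, rotation) combination exactly once, in
#' a random order subject to the replay constraint: every `UniCursor`
#' trial must occur later in the session than the `BiCursor` trial whose
#' cursor trajectory it replays (paired by rotation within the same
#' repetition set). Within each repetition set the rotations are mapped
#' onto the instructed directions by a freshly drawn random bijection, so
#' rotation and movement direction are decoupled across the session.
#'
#' The ordering constraint is enforced by shuffling each set uniformly
#' and then repairing violations: each offending `UniCursor` slot is
#' swapped with a slot chosen uniformly among later positions, repeated
#' until the set is admissible (with a bounded number of repair sweeps
#' before a full re-shuffle).
#'
#' @param spec A [design_spec()].
#' @param seed Optional integer seed; the slot sequence is reproducible
#'   for a fixed seed. `NULL` uses the current RNG state.
#' @param condition Optional condition label to stamp on the output
#'   (sessions are built per condition).
#' @return A tibble of trial slots with columns `session_index` (0-based
#'   position), `block`, `repetition_set`, `condition`, `trial_type`,
#'   `rotation_deg`, `instructed_direction_deg`, `source_slot` (for
#'   `UniCursor`, the `session_index` of the replayed `BiCursor` slot;
#'   `NA` otherwise).
#' @examples
#' sess <- build_session(design_spec(), seed = 1)
#' nrow(sess)  # 320
#' @export
build_session <- function(spec, seed = NULL, condition = NA_character_) {
  stopifnot(inherits(spec, "design_spec"))
  if ("UniCursor" %in% spec$trial_types &&
      !"BiCursor" %in% spec$trial_types) {
    stop("UniCursor trials replay BiCursor trajectories: ",
         "`trial_types` must include BiCursor.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  combos <- tidyr::expand_grid(
    trial_type = spec$trial_types,
    rotation_deg = spec$rotations_deg
  )
  n_set <- nrow(combos)
  n_rot <- length(spec$rotations_deg)

  sets <- lapply(seq_len(spec$n_repetitions), function(rep_i) {
    ord <- order_with_replay_constraint(combos)
    set <- combos[ord, ]
    # fresh rotation -> direction bijection per repetition set
    dirs <- if (length(spec$directions_deg) == n_rot) {
      sample(spec$directions_deg)
    } else {
      sample(spec$directions_deg, n_rot, replace = TRUE)
    }
    set$instructed_direction_deg <-
      dirs[match(set$rotation_deg, spec$rotations_deg)]
    set$repetition_set <- rep_i
    set
  })
  out <- dplyr::bind_rows(sets)
  n <- nrow(out)
  out$session_index <- seq_len(n) - 1L
  out$block <- as.integer(ceiling(seq_len(n) * spec$n_blocks / n))
  out$condition <- condition

  # resolve replay sources: BiCursor slot with the same rotation in the
  # same repetition set
  out$source_slot <- NA_integer_
  is_uc <- out$trial_type == "UniCursor"
  if (any(is_uc)) {
    bc <- out[out$trial_type == "BiCursor", ]
    key_uc <- paste(out$repetition_set[is_uc], out$rotation_deg[is_uc])
    key_bc <- paste(bc$repetition_set, bc$rotation_deg)
    out$source_slot[is_uc] <- bc$session_index[match(key_uc, key_bc)]
  }

  tibble::as_tibble(out[, c("session_index", "block", "repetition_set",
                            "condition", "trial_type", "rotation_deg",
                            "instructed_direction_deg", "source_slot")])
}

# Shuffle one repetition set and repair UniCursor-before-BiCursor
# violations by swapping offenders with uniformly chosen later slots.
order_with_replay_constraint <- function(combos, max_sweeps = 50L) {
  n <- nrow(combos)
  has_pair <- "UniCursor" %in% combos$trial_type &&
    "BiCursor" %in% combos$trial_type
  repeat {
    ord <- sample.int(n)
    if (!has_pair) return(ord)
    for (sweep in seq_len(max_sweeps)) {
      tt <- combos$trial_type[ord]
      rot <- combos$rotation_deg[ord]
      pos_uc <- which(tt == "UniCursor")
      pos_bc <- which(tt == "BiCursor")
      bad <- pos_uc[pos_uc < pos_bc[match(rot[pos_uc], rot[pos_bc])]]
      if (length(bad) == 0) return(ord)
      for (p in bad) {
        if (p >= n) next  # nothing later to swap with; retry next sweep
        q <- if (p + 1L == n) n else sample(seq(p + 1L, n), 1L)
        ord[c(p, q)] <- ord[c(q, p)]
      }
    }
    # irreparable within the sweep budget: re-shuffle from scratch
  }
}
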