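# Decision-to-command mapping and the meteor-evasion game simulator.

decision_direction <- function(d) {
  ifelse(d == "left", "left", ifelse(d == "right", "right", "idle"))
}

#' Map a decision stream to game commands
#'
#' Per decision, the base command is the majority vote over the mapped
#' directions (left/right/idle) of the last `window` decisions --- ties give
#' `idle` --- except that an idle-class decision (up, down, blink, center)
#' passes through immediately as `stop`: stopping must not lag. On top of the
#' base command, two successive identical directional decisions emit a
#' `speed_up` modifier and two successive opposite ones a `speed_down`
#' modifier. The majority window exists to absorb the gaze returning to
#' center after a saccade, which would otherwise read as a command in the
#' opposite direction.
#'
#' @param decisions Character vector of class decisions, or an
#'   `eog_decisions` tibble.
#' @param window Majority-vote window length (>= 1, default 3).
#' @return A tibble: `step`, `decision`, `command` (`move_left`,
#'   `move_right`, `stop`, `idle`), `modifier` (`none`, `speed_up`,
#'   `speed_down`).
#' @examples
#' map_decisions(c("left", "left", "blink"))$command
#' @export
map_decisions <- function(decisions, window = 3) {
  if (is.data.frame(decisions)) decisions <- decisions$decision
  if (window < 1) abort("window must be >= 1")
  n <- length(decisions)
  dirs <- decision_direction(decisions)
  command <- character(n)
  modifier <- rep("none", n)
  for (i in seq_len(n)) {
    if (dirs[i] == "idle") {
      command[i] <- "stop"
    } else {
      w <- dirs[max(1, i - window + 1):i]
      nl <- sum(w == "left"); nr <- sum(w == "right")
      command[i] <- if (nl > nr) "move_left" else if (nr > nl) "move_right" else "idle"
    }
    if (i > 1 && dirs[i] != "idle" && dirs[i - 1] != "idle") {
      modifier[i] <- if (dirs[i] == dirs[i - 1]) "speed_up" else "speed_down"
    }
  }
  tibble(step = seq_len(n), decision = decisions,
         command = command, modifier = modifier)
}

#' Create / update the character state
#'
#' The character's motion is a signed velocity vector `v` along x. Movement
#' commands integrate it in steps of `dv` = 0.1 units (left negative, right
#' positive), bounded by `v_max`; `stop`/`idle` zero it immediately in the
#' same step; `speed_up` adds `dv` to the magnitude preserving the sign and
#' `speed_down` removes `dv` from the magnitude, floored at zero. After the
#' command is applied the position advances by `v` (one step per 1-s
#' command).
#'
#' @param x,v Initial position and velocity.
#' @param dv Increment per command (default 0.1).
#' @param v_max Velocity bound (default 0.5).
#' @return A list of class `character_state`.
#' @export
character_state <- function(x = 0, v = 0, dv = 0.1, v_max = 0.5) {
  structure(list(x = x, v = v, dv = dv, v_max = v_max),
            class = "character_state")
}

#' @rdname character_state
#' @param state A `character_state`.
#' @param cmd One of `move_left`, `move_right`, `stop`, `idle`, `speed_up`,
#'   `speed_down`.
#' @param advance If `TRUE` (default) the position is advanced by `v` after
#'   applying the command; modifiers applied in the same step should use
#'   `advance = FALSE` on the first of the two applications.
#' @export
update_character <- function(state, cmd, advance = TRUE) {
  v <- state$v; dv <- state$dv
  v <- switch(cmd,
    move_left  = v - dv,
    move_right = v + dv,
    stop = 0, idle = 0,
    speed_up   = if (v == 0) 0 else sign(v) * (abs(v) + dv),
    speed_down = sign(v) * max(abs(v) - dv, 0),
    abort(paste0("unknown command: ", cmd)))
  v <- max(min(v, state$v_max), -state$v_max)
  state$v <- v
  if (advance) state$x <- state$x + v
  state
}

#' Integrate a command table into a trajectory
#'
#' Applies, per step, the base command and then any speed modifier, then
#' advances the position once.
#'
#' @param commands A tibble from [map_decisions()].
#' @param state Initial [character_state()].
#' @return A tibble `step`, `command`, `modifier`, `v`, `x`.
#' @export
run_character <- function(commands, state = character_state()) {
  out <- vector("list", nrow(commands))
  for (i in seq_len(nrow(commands))) {
    state <- update_character(state, commands$command[i], advance = FALSE)
    if (commands$modifier[i] != "none")
      state <- update_character(state, commands$modifier[i], advance = FALSE)
    state$x <- state$x + state$v
    out[[i]] <- tibble(step = commands$step[i], command = commands$command[i],
                       modifier = commands$modifier[i], v = state$v, x = state$x)
  }
  dplyr::bind_rows(out)
}

#' Initialise the meteor-evasion game
#'
#' A closed stage on x in \[-1, 1\] with five meteor release points evenly
#' spaced across the top. Meteors fall from y = 1 with downward acceleration
#' 0.01 units/step capped at a maximum speed of 0.1 units/step; at most five
#' are airborne at once. Each release point draws exponential inter-release
#' delays with a rate tuned so the five points together release on average 3
#' meteors per repetition (one repetition = the steps a meteor needs to
#' traverse the stage, 15 with these dynamics); a release attempt while five
#' are airborne is deferred, not dropped.
#'
#' @param seed RNG seed for the release schedule.
#' @param accel Downward acceleration per step (default 0.01).
#' @param vy_max Maximum fall speed per step (default 0.1).
#' @param max_meteors Concurrency cap (default 5).
#' @param releases_per_rep Mean releases per repetition (default 3).
#' @param n_points Number of release points (default 5).
#' @param char_width Character width for collision scoring (default 0.1).
#' @return A list of class `game_state`.
#' @export
game_state <- function(seed = 1, accel = 0.01, vy_max = 0.1, max_meteors = 5,
                       releases_per_rep = 3, n_points = 5, char_width = 0.1) {
  rep_steps <- traverse_steps(accel, vy_max)
  rate <- releases_per_rep / (n_points * rep_steps)
  set.seed(seed)
  gs <- list(
    t = 0L,
    character = character_state(),
    meteors = tibble(point = integer(), x = numeric(), y = numeric(),
                     vy = numeric()),
    next_release = 1 + stats::rexp(n_points, rate),
    points_x = seq(-1, 1, length.out = n_points),
    rate = rate, accel = accel, vy_max = vy_max,
    max_meteors = max_meteors, rep_steps = rep_steps,
    char_width = char_width,
    n_released = 0L, n_hits = 0L, n_landed = 0L
  )
  class(gs) <- "game_state"
  gs
}

# steps for a meteor to fall the unit stage height from rest
traverse_steps <- function(accel, vy_max) {
  y <- 1; vy <- 0; k <- 0
  while (y > 0) {
    vy <- min(vy + accel, vy_max)
    y <- y - vy
    k <- k + 1
  }
  k
}

#' Advance the game one step
#'
#' Order per step: the character applies `cmd` (and optional `modifier`) and
#' moves; meteors accelerate and fall; meteors reaching the ground are scored
#' (a hit if within half a character width of the character) and removed;
#' due releases fire, deferred while the concurrency cap is reached.
#'
#' @param gs A [game_state()].
#' @param cmd Command for this step (default `idle` keeps the character
#'   still).
#' @param modifier Optional speed modifier (`none`, `speed_up`,
#'   `speed_down`).
#' @return The updated `game_state`.
#' @export
step_game <- function(gs, cmd = "idle", modifier = "none") {
  gs$t <- gs$t + 1L
  gs$character <- update_character(gs$character, cmd, advance = FALSE)
  if (modifier != "none")
    gs$character <- update_character(gs$character, modifier, advance = FALSE)
  gs$character$x <- max(-1, min(1, gs$character$x + gs$character$v))

  if (nrow(gs$meteors)) {
    gs$meteors$vy <- pmin(gs$meteors$vy + gs$accel, gs$vy_max)
    gs$meteors$y <- gs$meteors$y - gs$meteors$vy
    landed <- gs$meteors$y <= 0
    if (any(landed)) {
      gs$n_landed <- gs$n_landed + sum(landed)
      gs$n_hits <- gs$n_hits +
        sum(abs(gs$meteors$x[landed] - gs$character$x) <= gs$char_width / 2)
      gs$meteors <- gs$meteors[!landed, ]
    }
  }
  for (p in seq_along(gs$next_release)) {
    while (gs$next_release[p] <= gs$t) {
      if (nrow(gs$meteors) >= gs$max_meteors) {
        gs$next_release[p] <- gs$t + 1      # defer, keep the release queued
        break
      }
      gs$meteors <- dplyr::bind_rows(
        gs$meteors,
        tibble(point = p, x = gs$points_x[p], y = 1, vy = 0))
      gs$n_released <- gs$n_released + 1L
      gs$next_release[p] <- gs$next_release[p] + stats::rexp(1, gs$rate)
    }
  }
  stopifnot(nrow(gs$meteors) <= gs$max_meteors)
  gs
}

#' Simulate a full game from a decision stream
#'
#' Maps decisions to commands ([map_decisions()]), optionally decimates them
#' (the controller consumes the first decision and ignores the second,
#' halving the command rate), and steps the game once per consumed command.
#'
#' @param decisions Character vector or `eog_decisions` tibble.
#' @param seed RNG seed for the meteor schedule.
#' @param window Majority-vote window (see [map_decisions()]).
#' @param control_decimation Consume every k-th command (default 2).
#' @param ... Passed to [game_state()].
#' @return A list of class `game_result`: `log` (tibble `step`, `command`,
#'   `modifier`, `v`, `x`, `n_meteors`), `state` (final `game_state`),
#'   `rates` (from [bit_rates()]).
#' @export
simulate_game <- function(decisions, seed = 1, window = 3,
                          control_decimation = 2, ...) {
  cmds <- map_decisions(decisions, window = window)
  consumed <- cmds[seq(1, nrow(cmds), by = control_decimation), , drop = FALSE]
  gs <- game_state(seed = seed, ...)
  log <- vector("list", nrow(consumed))
  for (i in seq_len(nrow(consumed))) {
    gs <- step_game(gs, consumed$command[i], consumed$modifier[i])
    log[[i]] <- tibble(step = i, command = consumed$command[i],
                       modifier = consumed$modifier[i],
                       v = gs$character$v, x = gs$character$x,
                       n_meteors = nrow(gs$meteors))
  }
  structure(list(log = dplyr::bind_rows(log), state = gs,
                 rates = bit_rates(length(decisions),
                                   duration_s = length(decisions),
                                   control_decimation = control_decimation)),
            class = "game_result")
}

#' @export
print.game_result <- function(x, ...) {
  cat(sprintf("<game_result> %d steps, %d meteors released, %d hits, final x = %.2f\n",
              nrow(x$log), x$state$n_released, x$state$n_hits, x$state$character$x))
  invisible(x)
}
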