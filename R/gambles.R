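#' Specify a standard gamble
#'
#' A gamble offers a certain `baseline` state against a lottery that yields
#' the better `win` state with probability `1 - p` and the worse `lose` state
#' with probability `p` (the probability of loss, taken from the ladder grid).
#' Gambles come in three design blocks: four adjacent-state personal-risk
#' gambles, four adjacent-state societal-inequality gambles, and four
#' personal gambles over non-adjacent triples used for overidentification.
#'
#' @param baseline,win,lose State labels; ranks must satisfy
#'   `lose < baseline < win`.
#' @param context `"personal"` or `"societal"`.
#' @param block `"adjacent_personal"`, `"adjacent_societal"` or
#'   `"nonadjacent_personal"`. Adjacent blocks require win and lose exactly
#'   one rank step from baseline; the nonadjacent block requires at least one
#'   arm more than one step (and at most three steps) away.
#' @return An object of class `sg_gamble`.
#' @examples
#' gamble_spec("E", "D", "F", "personal", "adjacent_personal")
#' @export
gamble_spec <- function(baseline, win, lose,
                        context = c("personal", "societal"),
                        block = c("adjacent_personal", "adjacent_societal",
                                  "nonadjacent_personal")) {
  context <- match.arg(context)
  block <- match.arg(block)
  rb <- state_rank(baseline); rw <- state_rank(win); rl <- state_rank(lose)
  if (!(rl < rb && rb < rw)) {
    stop("gamble states must satisfy rank(lose) < rank(baseline) < rank(win)",
         call. = FALSE)
  }
  up <- rw - rb; down <- rb - rl
  if (block %in% c("adjacent_personal", "adjacent_societal")) {
    if (up != 1L || down != 1L) {
      stop("adjacent-block gambles require win and lose one step from baseline",
           call. = FALSE)
    }
  } else {
    if (up > 3L || down > 3L || (up == 1L && down == 1L)) {
      stop("nonadjacent-block gambles need an arm 2-3 steps from baseline",
           call. = FALSE)
    }
  }
  if (context == "societal" && block != "adjacent_societal" ||
      context == "personal" && block == "adjacent_societal") {
    stop("block and context disagree", call. = FALSE)
  }
  structure(list(baseline = baseline, win = win, lose = lose,
                 context = context, block = block),
            class = "sg_gamble")
}

#' @export
print.sg_gamble <- function(x, ...) {
  cat(sprintf("<gamble> %s vs. %s/%s (%s)\n",
              x$baseline, x$win, x$lose, x$block))
  invisible(x)
}

gamble_label <- function(g) {
  sprintf("%s vs. %s/%s", g$baseline, g$win, g$lose)
}

#' The four adjacent chained gambles for one context
#'
#' Baselines E, D, C, B in ascending order; each gamble's win and lose states
#' are the adjacent states, so the chain `E vs. D/F`, `D vs. C/E`,
#' `C vs. B/D`, `B vs. A/C` identifies all six state utilities given the two
#' anchors.
#'
#' @param context `"personal"` or `"societal"`.
#' @return List of four `sg_gamble` objects.
#' @export
adjacent_gambles <- function(context = c("personal", "societal")) {
  context <- match.arg(context)
  block <- if (context == "personal") "adjacent_personal" else "adjacent_societal"
  lapply(2:5, function(r) {
    gamble_spec(.sg_states[r], .sg_states[r + 1L], .sg_states[r - 1L],
                context, block)
  })
}

#' All valid non-adjacent gamble triples
#'
#' Triples `(baseline, win, lose)` with states up to three rank steps apart
#' and at least one arm more than one step from the baseline.
#'
#' @return Data frame with columns `baseline`, `win`, `lose`.
#' @export
nonadjacent_triples <- function() {
  out <- expand.grid(bl = 2:5, up = 1:3, down = 1:3)
  out <- out[out$bl + out$up <= 6L & out$bl - out$down >= 1L &
               !(out$up == 1L & out$down == 1L), , drop = FALSE]
  data.frame(baseline = .sg_states[out$bl],
             win = .sg_states[out$bl + out$up],
             lose = .sg_states[out$bl - out$down],
             stringsAsFactors = FALSE)
}
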