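#' A descending-probability choice ladder
#'
#' One gamble is presented repeatedly down the probability grid, starting at
#' loss probability 1/2. A rejection advances to the next lower probability; an
#' acceptance ends the ladder; a `cant_choose` is followed by the next lower
#' probability, and two consecutive `cant_choose` responses (or a
#' `cant_choose` at the lowest grid value, where no lower probability exists)
#' mark the gamble undecidable.
#'
#' @param gamble An `sg_gamble`.
#' @param decisions Character vector over the presented grid prefix, each
#'   element one of `"accept"`, `"reject"`, `"cant_choose"`.
#' @return Object of class `sg_ladder`.
#' @examples
#' g <- gamble_spec("E", "D", "F", "personal", "adjacent_personal")
#' ladder_response(g, c("reject", "accept"))
#' @export
ladder_response <- function(gamble, decisions) {
  stopifnot(inherits(gamble, "sg_gamble"))
  n <- length(decisions)
  if (n < 1L || n > 8L) {
    stop("ladder must have between 1 and 8 decisions", call. = FALSE)
  }
  ok <- decisions %in% c("accept", "reject", "cant_choose")
  if (!all(ok)) {
    stop("invalid decision value(s): ",
         paste(unique(decisions[!ok]), collapse = ", "), call. = FALSE)
  }
  acc <- which(decisions == "accept")
  if (length(acc) > 1L || (length(acc) == 1L && acc != n)) {
    stop("an accept ends the ladder; decisions may contain at most one, last",
         call. = FALSE)
  }
  und <- .ladder_undecidable(decisions)
  if (und$where > 0L && und$where < n) {
    stop("decisions continue past an undecidable point", call. = FALSE)
  }
  terminal <- length(acc) == 1L || n == 8L || und$undecidable
  if (!terminal) {
    stop("ladder ends without accept, grid exhaustion, or undecidability",
         call. = FALSE)
  }
  structure(list(gamble = gamble,
                 decisions = decisions,
                 p = .sg_grid_values[seq_len(n)],
                 p_label = .sg_grid_labels[seq_len(n)],
                 undecidable = und$undecidable),
            class = "sg_ladder")
}

# Two consecutive cant_choose, or cant_choose with no lower probability left.
.ladder_undecidable <- function(decisions) {
  n <- length(decisions)
  cc <- decisions == "cant_choose"
  if (n >= 2L) {
    run <- which(cc[-1L] & cc[-n]) + 1L
    if (length(run)) return(list(undecidable = TRUE, where = run[1L]))
  }
  if (cc[n] && n == 8L) return(list(undecidable = TRUE, where = n))
  list(undecidable = cc[n], where = if (cc[n]) n else 0L)
}

#' @export
print.sg_ladder <- function(x, ...) {
  cat(sprintf("<ladder> %s: %s%s\n", gamble_label(x$gamble),
              paste(substr(x$decisions, 1, 1), collapse = ""),
              if (x$undecidable) " (undecidable)" else ""))
  invisible(x)
}

#' Indifference probability from a choice ladder
#'
#' The indifference point is the geometric (log-scale) midpoint of the highest
#' accepted loss probability and the lowest rejected one:
#' `p = sqrt(p_accept_max * p_reject_min)`, with `p_accept_max = 0` if no
#' step was accepted (rejecting even 1-in-a-million, read as infinite
#' aversion) and `p_reject_min = 1` if none was rejected. Accepting the very
#' first step (loss probability 1/2) therefore yields `p = sqrt(0.5)`, the
#' maximal tolerance the ladder can express.
#'
#' @param ladder An `sg_ladder`.
#' @return List of class `sg_indiff` with elements `p` (numeric, `NA` when
#'   undecidable) and `status` (`"interior"`, `"infinite_aversion"`,
#'   `"maximal_tolerance"` or `"undecidable"`).
#' @examples
#' g <- gamble_spec("E", "D", "F", "personal", "adjacent_personal")
#' indifference_probability(ladder_response(g, c("reject", "accept")))
#' @export
indifference_probability <- function(ladder) {
  stopifnot(inherits(ladder, "sg_ladder"))
  if (ladder$undecidable) {
    return(structure(list(p = NA_real_, status = "undecidable"),
                     class = "sg_indiff"))
  }
  acc <- ladder$p[ladder$decisions == "accept"]
  rej <- ladder$p[ladder$decisions == "reject"]
  p_acc <- if (length(acc)) max(acc) else 0
  p_rej <- if (length(rej)) min(rej) else 1
  p <- sqrt(p_acc * p_rej)
  status <- if (p_acc == 0) {
    "infinite_aversion"
  } else if (ladder$decisions[1L] == "accept") {
    "maximal_tolerance"
  } else {
    "interior"
  }
  structure(list(p = p, status = status), class = "sg_indiff")
}

#' @export
print.sg_indiff <- function(x, ...) {
  cat(sprintf("<indifference> p = %s (%s)\n",
              if (is.na(x$p)) "NA" else format(x$p, digits = 5), x$status))
  invisible(x)
}
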