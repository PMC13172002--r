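#' Write respondents to a long-format CSV
#'
#' One row per (participant, gamble, ladder step); participant scalars
#' (condition, demographics, political items, vignette ratings) are repeated
#' on every row so a single UTF-8 CSV survives variable ladder lengths
#' losslessly. Probabilities are written as exact fraction labels.
#'
#' @param respondents List of `sg_respondent` objects (may be empty, which
#'   yields a header-only file).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_respondents()] for the inverse; the round trip is the
#'   identity on valid data.
#' @export
write_respondents <- function(respondents, path) {
  rows <- lapply(respondents, function(r) {
    lad <- lapply(seq_along(r$ladders), function(gi) {
      l <- r$ladders[[gi]]
      n <- length(l$decisions)
      data.frame(id = rep(as.character(r$id), n),
                 condition = r$condition, age_band = r$age_band, sex = r$sex,
                 party = r$party,
                 pol1 = r$political_items[1], pol2 = r$political_items[2],
                 pol3 = r$political_items[3], pol4 = r$political_items[4],
                 pol5 = r$political_items[5],
                 rate_A = r$vignette_ratings[["A"]],
                 rate_B = r$vignette_ratings[["B"]],
                 rate_C = r$vignette_ratings[["C"]],
                 rate_D = r$vignette_ratings[["D"]],
                 rate_E = r$vignette_ratings[["E"]],
                 attention_fail = r$flags$attention_fail,
                 gamble_index = gi,
                 context = l$gamble$context, block = l$gamble$block,
                 baseline = l$gamble$baseline, win = l$gamble$win,
                 lose = l$gamble$lose,
                 step_index = seq_len(n), p_loss = l$p_label,
                 decision = l$decisions,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, lad)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else .respondent_csv_skeleton()
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

.respondent_csv_cols <- c("id", "condition", "age_band", "sex", "party",
                          "pol1", "pol2", "pol3", "pol4", "pol5",
                          "rate_A", "rate_B", "rate_C", "rate_D", "rate_E",
                          "attention_fail", "gamble_index", "context",
                          "block", "baseline", "win", "lose",
                          "step_index", "p_loss", "decision")

.respondent_csv_skeleton <- function() {
  out <- lapply(.respondent_csv_cols, function(x) character(0))
  names(out) <- .respondent_csv_cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read respondents from a long-format CSV
#'
#' Inverse of [write_respondents()]. Every respondent invariant (12 ladders
#' with the required block composition, integer ratings, grid probabilities,
#' ladder stopping rules) is enforced; a malformed respondent is reported with
#' the offending participant id and first file row rather than silently
#' coerced.
#'
#' @param path CSV file written in the documented schema.
#' @return List of `sg_respondent` objects.
#' @export
read_respondents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.respondent_csv_cols, names(tab))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(list())
  tab$id <- as.character(tab$id)
  tab$p_loss <- as.character(tab$p_loss)
  parse_probability(unique(tab$p_loss))  # format error early, before split
  tab$.row <- seq_len(nrow(tab)) + 1L    # file line numbers (header is row 1)
  ids <- unique(tab$id)
  lapply(ids, function(pid) {
    sub <- tab[tab$id == pid, , drop = FALSE]
    first_row <- min(sub$.row)
    out <- tryCatch(.parse_respondent(sub), error = function(e) e)
    if (inherits(out, "error")) {
      stop(sprintf("respondent '%s' (file row %d): %s",
                   pid, first_row, conditionMessage(out)), call. = FALSE)
    }
    out
  })
}

.parse_respondent <- function(sub) {
  head1 <- sub[1L, ]
  ladders <- lapply(split(sub, sub$gamble_index), function(g) {
    g <- g[order(g$step_index), , drop = FALSE]
    if (!identical(g$step_index, seq_len(nrow(g)))) {
      stop("ladder steps are not a contiguous 1..n sequence")
    }
    if (!identical(g$p_loss, .sg_grid_labels[seq_len(nrow(g))])) {
      stop("ladder probabilities must follow the descending grid")
    }
    ladder_response(gamble_spec(g$baseline[1L], g$win[1L], g$lose[1L],
                                g$context[1L], g$block[1L]),
                    g$decision)
  })
  respondent(id = head1$id, condition = head1$condition,
             age_band = head1$age_band, sex = head1$sex, party = head1$party,
             political_items = c(head1$pol1, head1$pol2, head1$pol3,
                                 head1$pol4, head1$pol5),
             vignette_ratings = c(A = head1$rate_A, B = head1$rate_B,
                                  C = head1$rate_C, D = head1$rate_D,
                                  E = head1$rate_E),
             ladders = unname(ladders),
             attention_fail = head1$attention_fail)
}

#' Read a binned life-satisfaction distribution
#'
#' Expects a CSV with columns `ls_range` and `share` (optionally
#' `representative_ls`) whose rows are exactly the bins 0-4, 5-6, 7-8 and
#' 9-10, in any order.
#'
#' @param path CSV file.
#' @param normalise Passed to [binned_ls_distribution()].
#' @return An `ls_distribution`.
#' @export
read_distribution <- function(path, normalise = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ls_range", "share") %in% names(tab))) {
    stop("schema error: need columns ls_range, share", call. = FALSE)
  }
  want <- c("0-4", "5-6", "7-8", "9-10")
  idx <- match(want, tab$ls_range)
  if (nrow(tab) != 4L || anyNA(idx)) {
    stop("distribution must contain exactly the bins 0-4, 5-6, 7-8, 9-10",
         call. = FALSE)
  }
  rep_ls <- if ("representative_ls" %in% names(tab)) {
    tab$representative_ls[idx]
  } else {
    c(2, 5.5, 7.5, 9.5)
  }
  binned_ls_distribution(tab$share[idx], rep_ls, normalise = normalise)
}

#' Write a binned life-satisfaction distribution
#' @param dist An `ls_distribution`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "ls_distribution"))
  utils::write.csv(data.frame(ls_range = dist$ranges, share = dist$shares,
                              representative_ls = dist$representative_ls),
                   path, row.names = FALSE)
  invisible(path)
}
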