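# Ensemble voting rules for two-class model committees. Data-agnostic: the
# inputs are the member models' predicted labels (hard voting) or their
# predicted class-A probabilities (soft voting).

.vote_result <- function(method, winner, percent) {
  structure(
    list(method = method, winner = winner, percent = percent),
    class = "vote_result"
  )
}

#' @export
print.vote_result <- function(x, ...) {
  cat("<vote_result> ", x$method, " voting: class ", x$winner, "\n", sep = "")
  for (cl in names(x$percent)) {
    cat("  ", cl, ": ", sprintf("%.1f%%", x$percent[[cl]]), "\n", sep = "")
  }
  invisible(x)
}

#' Hard (majority) voting
#'
#' The winning class is the modal label. A tie breaks toward the class that
#' sorts first (so with labels A and B, toward A).
#'
#' @param labels Nonempty character vector of predicted class labels, one per
#'   committee member.
#' @return A `vote_result` with the winner and each class's vote share as a
#'   percentage rounded to one decimal.
#' @examples
#' hard_vote(c("A", "A", "A", "B", "B")) # class A, 60% / 40%
#' @export
hard_vote <- function(labels) {
  if (length(labels) == 0L) stop("need at least one label", call. = FALSE)
  labels <- as.character(labels)
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  winner <- sort(winners)[1L]
  percent <- round(100 * as.numeric(tab) / length(labels), 1)
  names(percent) <- names(tab)
  .vote_result("hard", winner, as.list(percent))
}

#' Soft (probability-averaging) voting
#'
#' The class-A score is 100 times the mean of the members' predicted class-A
#' probabilities; the class-B score is its complement. The larger score wins;
#' an exact tie breaks toward the first class.
#'
#' @param probs Numeric vector of class-A probabilities in `[0, 1]`, one per
#'   committee member.
#' @param labels Length-2 character vector naming the two classes.
#' @return A `vote_result` with per-class percentages rounded to one decimal.
#' @examples
#' soft_vote(c(0.84, 0.90, 0.65, 0.89, 0.54)) # class A at 76.4%
#' @export
soft_vote <- function(probs, labels = c("A", "B")) {
  if (length(probs) == 0L) stop("need at least one probability", call. = FALSE)
  if (!is.numeric(probs) || any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(labels) != 2L) stop("exactly two class labels required", call. = FALSE)
  pa <- mean(probs)
  pb <- mean(1 - probs)
  winner <- if (pa >= pb) labels[1L] else labels[2L]
  percent <- list(round(100 * pa, 1), round(100 * pb, 1))
  names(percent) <- labels
  .vote_result("soft", winner, percent)
}
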