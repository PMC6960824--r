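#' Per-radar class probabilities
#'
#' Container for the two softmax outputs of the classifier on one record from
#' one radar. Probabilities must be in `[0, 1]` and sum to 1 (tolerance
#' 1e-6).
#'
#' @param p_fall,p_not_fall Softmax probabilities.
#' @param radar_id Source radar id.
#' @param record_id Record identifier (or the shared event identifier when
#'   used for fusion).
#' @return Object of class `class_probabilities`.
#' @export
class_probabilities <- function(p_fall, p_not_fall, radar_id = NA_integer_,
                                record_id = NA_character_) {
  stopifnot(
    p_fall >= 0, p_fall <= 1, p_not_fall >= 0, p_not_fall <= 1,
    abs(p_fall + p_not_fall - 1) <= 1e-6
  )
  structure(
    list(
      p_fall = p_fall, p_not_fall = p_not_fall,
      radar_id = radar_id, record_id = record_id
    ),
    class = "class_probabilities"
  )
}

#' Fuse two radars' class probabilities into one decision
#'
#' Decision-level fusion of the per-radar softmax outputs for one event. The
#' default `"max"` rule picks the class attaining the single highest
#' probability among the four values (the most literal reading of "the output
#' class was picked as the class with the highest probability"); `"mean"`
#' averages per class and takes the argmax. An exact tie resolves to
#' `"not_fall"`, a conservative bias against false alarms. Fusion is
#' symmetric in the two radars.
#'
#' @param probs_1,probs_2 [class_probabilities()] for the same event from the
#'   two radars. Mismatched `record_id`s are rejected.
#' @param rule `"max"` (default) or `"mean"`.
#' @return `"fall"` or `"not_fall"`.
#' @examples
#' p1 <- class_probabilities(0.9, 0.1, 1, "e1")
#' p2 <- class_probabilities(0.2, 0.8, 2, "e1")
#' fuse_decision(p1, p2) # "fall": 0.9 is the single highest probability
#' @export
fuse_decision <- function(probs_1, probs_2, rule = c("max", "mean")) {
  rule <- match.arg(rule)
  stopifnot(
    inherits(probs_1, "class_probabilities"),
    inherits(probs_2, "class_probabilities")
  )
  r1 <- probs_1$record_id
  r2 <- probs_2$record_id
  if (!is.na(r1) && !is.na(r2) && r1 != r2) {
    stop("record ids do not refer to the same event: '", r1, "' vs '", r2, "'")
  }
  fuse_prob_pair(
    c(probs_1$p_fall, probs_2$p_fall),
    c(probs_1$p_not_fall, probs_2$p_not_fall),
    rule
  )
}

# Vector core shared by fuse_decision and the experiment loop.
fuse_prob_pair <- function(p_fall, p_not_fall, rule) {
  if (rule == "max") {
    f <- max(p_fall)
    n <- max(p_not_fall)
  } else {
    f <- mean(p_fall)
    n <- mean(p_not_fall)
  }
  if (f > n) "fall" else "not_fall" # tie -> not_fall
}
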