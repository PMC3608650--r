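## Quality control of crowdsourced representativeness ratings: check-trial
## discount scores, rater and image exclusion, and exemplar-set selection.

#' Check-trial discount scores per rater
#'
#' For every check trial (a repeat of an image the same rater saw within the
#' preceding 10 trials), the contribution is 5 when the category response
#' differs from the original response, and otherwise the absolute difference
#' between the new and old rating. Contributions are summed per rater.
#'
#' @param ratings Rating table as produced by [generate_rating_table()]
#'   (columns `rater_id`, `trial`, `image_id`, `response`, `rating`,
#'   `is_check`, `refers_to`).
#' @return List of class `discount_ledger`: `totals` (data.frame `rater_id`,
#'   `discount`) and `contributions` (one row per check trial with its
#'   contribution).
#' @export
discount_score <- function(ratings) {
  req <- c("rater_id", "trial", "response", "rating", "is_check", "refers_to")
  if (!all(req %in% names(ratings))) {
    stop("rating table is missing required columns", call. = FALSE)
  }
  checks <- ratings[ratings$is_check, , drop = FALSE]
  contribs <- lapply(seq_len(nrow(checks)), function(i) {
    row <- checks[i, ]
    ref <- ratings[ratings$rater_id == row$rater_id &
                   ratings$trial == row$refers_to, , drop = FALSE]
    if (nrow(ref) != 1L) {
      stop(sprintf("check trial %d of %s references missing trial %s",
                   row$trial, row$rater_id, row$refers_to), call. = FALSE)
    }
    contribution <- if (!identical(row$response, ref$response)) {
      5
    } else {
      abs(row$rating - ref$rating)
    }
    data.frame(rater_id = row$rater_id, trial = row$trial,
               refers_to = row$refers_to, contribution = contribution,
               stringsAsFactors = FALSE)
  })
  contribs <- if (length(contribs)) do.call(rbind, contribs) else
    data.frame(rater_id = character(0), trial = integer(0),
               refers_to = integer(0), contribution = numeric(0))
  all_raters <- unique(ratings$rater_id)
  totals <- vapply(all_raters, function(r) {
    sum(contribs$contribution[contribs$rater_id == r])
  }, numeric(1))
  structure(
    list(totals = data.frame(rater_id = all_raters, discount = unname(totals),
                             stringsAsFactors = FALSE),
         contributions = contribs),
    class = "discount_ledger"
  )
}

#' Exclude inconsistent raters
#'
#' Retains raters whose total discount score does not exceed the threshold
#' (strict inequality: a total of exactly `threshold` is retained).
#'
#' @param ledger A `discount_ledger` from [discount_score()].
#' @param threshold Exclusion threshold (default 10).
#' @return Character vector of retained rater ids.
#' @export
filter_raters <- function(ledger, threshold = 10) {
  stopifnot(inherits(ledger, "discount_ledger"))
  keep <- ledger$totals$discount <= threshold
  ledger$totals$rater_id[keep]
}

#' Exclude images rated out of category too often
#'
#' An image is dropped when the fraction of ratings assigning it to a
#' different category (or to "none of them") strictly exceeds `fraction` of
#' its total ratings.
#'
#' @param image_responses data.frame with columns `image_id`, `category`
#'   (the image's nominal category) and `response` (a category label or
#'   `"none"`); one row per rating.
#' @param fraction Exclusion fraction (default 1/4).
#' @return Character vector of retained image ids.
#' @export
filter_images <- function(image_responses, fraction = 1 / 4) {
  req <- c("image_id", "category", "response")
  if (!all(req %in% names(image_responses))) {
    stop("`image_responses` must have columns image_id, category, response",
         call. = FALSE)
  }
  ids <- unique(image_responses$image_id)
  keep <- vapply(ids, function(id) {
    rows <- image_responses[image_responses$image_id == id, ]
    if (nrow(rows) < 1L) return(FALSE)
    non_member <- sum(rows$response != rows$category)
    non_member <= fraction * nrow(rows)
  }, logical(1))
  ids[keep]
}

#' Select good, medium and bad exemplar sets from ranked candidates
#'
#' From 240 candidates (80 good-candidates, 80 medium-candidates, 80
#' bad-candidates) ranked by descending mean rating: the good set is the 60
#' highest-rated of the good candidates, the bad set the 60 lowest-rated of
#' the bad candidates, and the medium set the 60 central images (ranks
#' 91-150) of the full ranked list. Ties in mean rating are broken by image
#' id for a deterministic ranking. The three sets must come out mutually
#' exclusive (they do whenever the candidate classes are ordered in rating,
#' as in real data); overlap raises an error.
#'
#' @param candidates data.frame with columns `image_id`, `candidate_class`
#'   (good/medium/bad) and `mean_rating`; exactly 240 rows, 80 per class,
#'   no duplicated ids.
#' @return List of class `exemplar_sets` with `good`, `medium`, `bad`
#'   (character vectors of 60 ids each) and the full `ranking`.
#' @export
select_exemplar_sets <- function(candidates) {
  req <- c("image_id", "candidate_class", "mean_rating")
  if (!all(req %in% names(candidates))) {
    stop("`candidates` must have columns image_id, candidate_class, mean_rating",
         call. = FALSE)
  }
  if (nrow(candidates) != 240L || anyDuplicated(candidates$image_id)) {
    stop("expected exactly 240 candidates with unique image ids", call. = FALSE)
  }
  class_counts <- table(candidates$candidate_class)
  if (!setequal(names(class_counts), c("good", "medium", "bad")) ||
      any(class_counts != 80L)) {
    stop("expected 80 candidates in each of good/medium/bad", call. = FALSE)
  }
  ord <- order(-candidates$mean_rating, candidates$image_id)
  ranked <- candidates[ord, , drop = FALSE]
  good_pool <- ranked[ranked$candidate_class == "good", ]
  bad_pool <- ranked[ranked$candidate_class == "bad", ]
  good <- head(good_pool$image_id, 60L)
  bad <- tail(bad_pool$image_id, 60L)
  medium <- ranked$image_id[91:150]
  sets <- list(good = good, medium = medium, bad = bad)
  if (length(unique(unlist(sets))) != 180L) {
    stop("selected exemplar sets overlap; candidate ratings do not separate the classes",
         call. = FALSE)
  }
  structure(c(sets, list(ranking = ranked$image_id)), class = "exemplar_sets")
}
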