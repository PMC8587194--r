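# Linkage of review streams and report-card issues to the
# surgeon-by-quarter information states a patient could have seen at
# admission time.  All dates are integer study quarters (1-based).

#' Running average star rating visible at a given quarter
#'
#' Arithmetic mean of a surgeon's overall star ratings over reviews posted
#' before the admission quarter.  By default only reviews posted in
#' strictly earlier quarters count (information available at decision
#' time); set `include_same_quarter = TRUE` to also count reviews posted
#' during the admission quarter itself.
#'
#' @param reviews data frame with columns `surgeon_id`, `quarter`,
#'   `stars` (integers 1-5).
#' @param surgeon_id surgeon to look up.  An id never seen in `reviews`
#'   yields `NA` (never reviewed).
#' @param quarter admission quarter.
#' @param include_same_quarter logical; count same-quarter reviews?
#' @return the average rating, or `NA_real_` if no qualifying review.
#' @export
average_rating_at <- function(reviews, surgeon_id, quarter,
                              include_same_quarter = FALSE) {
  stopifnot(is.data.frame(reviews),
            all(c("surgeon_id", "quarter", "stars") %in% names(reviews)))
  if (nrow(reviews) > 0 && any(!reviews$stars %in% 1:5))
    stop("average_rating_at: stars must be integers in 1..5")
  keep <- reviews$surgeon_id == surgeon_id &
    (if (include_same_quarter) reviews$quarter <= quarter
     else reviews$quarter < quarter)
  if (!any(keep)) return(NA_real_)
  mean(reviews$stars[keep])
}

#' Classify an average star rating into an online information state
#'
#' A surgeon is "high" rated in a quarter when the running average is at
#' least four stars (boundary inclusive), "low" below four stars, and
#' "none" when not yet reviewed (`NA` average).
#'
#' @param average numeric vector of average ratings in `[1, 5]`, with
#'   `NA` for surgeons not yet reviewed.
#' @return character vector over `{"high", "low", "none"}`.
#' @export
classify_online <- function(average) {
  bad <- !is.na(average) & (average < 1 | average > 5)
  if (any(bad))
    stop("classify_online: average rating outside [1, 5]: ",
         paste(average[bad], collapse = ", "))
  out <- rep("none", length(average))
  out[!is.na(average) & average >= 4] <- "high"
  out[!is.na(average) & average < 4] <- "low"
  out
}

#' Report-card issue in effect at a given quarter
#'
#' Each issue is effective from its publication quarter (inclusive) until
#' the next issue's publication quarter (exclusive); the final issue stays
#' effective through the end of the window.
#'
#' @param report_cards data frame with columns `pub_quarter`,
#'   `surgeon_id`, `category` (one row per rated surgeon per issue).
#' @param quarter admission quarter.
#' @return the rows of the effective issue, or `NULL` if `quarter`
#'   precedes the first publication.
#' @export
effective_report_card <- function(report_cards, quarter) {
  stopifnot(is.data.frame(report_cards))
  if (nrow(report_cards) == 0) return(NULL)
  pubs <- sort(unique(report_cards$pub_quarter))
  i <- findInterval(quarter, pubs)
  if (i == 0) return(NULL)
  report_cards[report_cards$pub_quarter == pubs[i], , drop = FALSE]
}

#' Classify a surgeon's report-card state under an issue
#'
#' "high" when the effective issue scores the surgeon as having
#' lower-than-expected mortality; "not_high" for as-expected or
#' greater-than-expected; "none" when no issue is in effect or the
#' surgeon is unrated in it (below the case-volume threshold).
#'
#' @param issue rows of one report-card issue (from
#'   [effective_report_card()]), or `NULL`.
#' @param surgeon_id character vector of surgeons to classify.
#' @return character vector over `{"high", "not_high", "none"}`.
#' @export
classify_report <- function(issue, surgeon_id) {
  if (is.null(issue) || nrow(issue) == 0)
    return(rep("none", length(surgeon_id)))
  ok <- c("lower_than_expected", "as_expected", "greater_than_expected")
  if (any(!issue$category %in% ok))
    stop("classify_report: unknown category: ",
         paste(setdiff(issue$category, ok), collapse = ", "))
  m <- match(surgeon_id, issue$surgeon_id)
  out <- rep("none", length(surgeon_id))
  rated <- !is.na(m)
  out[rated] <- ifelse(issue$category[m[rated]] == "lower_than_expected",
                       "high", "not_high")
  out
}

#' Build the full surgeon-by-quarter quality panel
#'
#' Applies [average_rating_at()], [classify_online()] and
#' [classify_report()] over the complete `surgeon_ids x quarters` grid.
#' Within a quarter a surgeon carries one online state and one report
#' state, shared across all hospitals where the surgeon practices.
#'
#' @param reviews review stream (`surgeon_id`, `quarter`, `stars`).
#' @param report_cards report-card issue rows (`pub_quarter`,
#'   `surgeon_id`, `category`).
#' @param surgeon_ids character vector of all surgeons.
#' @param quarters integer vector of study quarters.
#' @param include_same_quarter passed to the running-average convention.
#' @return data frame with one row per (surgeon, quarter):
#'   `surgeon_id`, `quarter`, `avg_rating`, `online_state`,
#'   `report_state`.
#' @export
build_quality_panel <- function(reviews, report_cards, surgeon_ids, quarters,
                                include_same_quarter = FALSE) {
  surgeon_ids <- as.character(surgeon_ids)
  quarters <- sort(unique(as.integer(quarters)))
  stopifnot(length(surgeon_ids) > 0, length(quarters) > 0)
  qmax <- max(quarters)
  S <- length(surgeon_ids)

  # cumulative review count/sum per surgeon over quarters 1..qmax
  cnt <- matrix(0, S, qmax, dimnames = list(surgeon_ids, NULL))
  sm <- cnt
  if (nrow(reviews) > 0) {
    sid <- match(as.character(reviews$surgeon_id), surgeon_ids)
    unknown <- is.na(sid)
    if (any(unknown))
      message("build_quality_panel: ignoring ", sum(unknown),
              " review(s) for surgeons outside the roster")
    rq <- as.integer(reviews$quarter)[!unknown]
    rs <- as.numeric(reviews$stars)[!unknown]
    si <- sid[!unknown]
    inwin <- rq >= 1 & rq <= qmax
    for (i in which(inwin)) {
      cnt[si[i], rq[i]] <- cnt[si[i], rq[i]] + 1
      sm[si[i], rq[i]] <- sm[si[i], rq[i]] + rs[i]
    }
  }
  ccnt <- t(apply(cnt, 1, cumsum))
  csm <- t(apply(sm, 1, cumsum))

  # information available at quarter q: reviews posted < q (or <= q)
  avail_at <- function(m, q) {
    qq <- if (include_same_quarter) q else q - 1L
    if (qq < 1) rep(0, nrow(m)) else m[, qq]
  }

  pubs <- if (nrow(report_cards) > 0) sort(unique(report_cards$pub_quarter))
          else integer(0)

  out <- vector("list", length(quarters))
  for (qi in seq_along(quarters)) {
    q <- quarters[qi]
    n <- avail_at(ccnt, q)
    s <- avail_at(csm, q)
    avg <- ifelse(n > 0, s / n, NA_real_)
    issue <- if (length(pubs) > 0) effective_report_card(report_cards, q)
             else NULL
    out[[qi]] <- data.frame(
      surgeon_id = surgeon_ids,
      quarter = q,
      avg_rating = avg,
      online_state = classify_online(avg),
      report_state = classify_report(issue, surgeon_ids),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$surgeon_id, res$quarter), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a reviews CSV (surgeon_id, quarter, stars)
#' @param path file path.
#' @return data frame of reviews.
#' @export
read_reviews <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("surgeon_id", "quarter", "stars") %in% names(x)))
  x$quarter <- as.integer(x$quarter)
  x$stars <- as.integer(x$stars)
  x
}

#' Read a report-card CSV (pub_quarter, surgeon_id, category)
#' @param path file path.
#' @return data frame of report-card rows.
#' @export
read_report_cards <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pub_quarter", "surgeon_id", "category") %in% names(x)))
  x$pub_quarter <- as.integer(x$pub_quarter)
  x
}
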