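#' Load the BWS clinical feature vocabulary
#'
#' The controlled vocabulary behind [score_bws()]: cardinal (2-point) and
#' suggestive (1-point) feature categories with case-insensitive regex
#' synonym patterns and optional exclusions, shipped as an editable YAML
#' resource.
#'
#' @param path YAML file; defaults to the packaged vocabulary.
#' @return nested list with components `cardinal` and `suggestive`.
#' @export
bws_feature_vocabulary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bws_features.yaml", package = "mlidscan",
                        mustWork = TRUE)
  vocab <- yaml::read_yaml(path)
  stopifnot(all(c("cardinal", "suggestive") %in% names(vocab)))
  vocab
}

match_category <- function(features, cat) {
  hit <- rep(FALSE, length(features))
  for (p in cat$patterns)
    hit <- hit | grepl(p, features, ignore.case = TRUE)
  for (ex in cat$exclude %||% character())
    hit <- hit & !grepl(ex, features, ignore.case = TRUE)
  any(hit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-tier Beckwith-Wiedemann clinical score
#'
#' Score = 2 x (distinct cardinal categories present) + 1 x (distinct
#' suggestive categories present). Each category counts at most once
#' regardless of how many features map to it; features matching no category
#' contribute nothing (non-scoring signs such as prognathism or strabismus
#' by design, unrecognized tokens with a message when `quiet = FALSE`).
#'
#' @param features character vector of free-text clinical features.
#' @param vocab vocabulary from [bws_feature_vocabulary()].
#' @param quiet suppress the message listing non-scoring features.
#' @return integer score; the matched category names are attached as
#'   attributes `cardinal` and `suggestive`.
#' @examples
#' score_bws(c("macroglossia", "macrosomia"))  # 3
#' @export
score_bws <- function(features, vocab = bws_feature_vocabulary(), quiet = TRUE) {
  features <- trimws(as.character(features))
  features <- features[nzchar(features)]
  card <- names(vocab$cardinal)[vapply(vocab$cardinal, match_category,
                                       TRUE, features = features)]
  sugg <- names(vocab$suggestive)[vapply(vocab$suggestive, match_category,
                                         TRUE, features = features)]
  if (!quiet) {
    all_cats <- c(vocab$cardinal, vocab$suggestive)
    scored <- vapply(features, function(f)
      any(vapply(all_cats, match_category, TRUE, features = f)), TRUE)
    if (any(!scored))
      message("non-scoring feature(s): ", paste(features[!scored], collapse = "; "))
  }
  structure(2L * length(card) + length(sugg),
            cardinal = card, suggestive = sugg)
}
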