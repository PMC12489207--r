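#' Load a homophone dictionary
#'
#' A homophone dictionary maps word forms that a general-purpose speech
#' recognizer may emit ("ate", "for", "sex", ...) to the digit the speaker
#' almost certainly said. The file format is one `word<TAB>digit` entry per
#' line (UTF-8, `#` comments allowed), so the curated dictionary shipped
#' with the package can be swapped for any other confusion list without code
#' changes. The canonical digit words ("zero".."nine") and the numerals
#' ("0".."9") always resolve, whether or not the file lists them.
#'
#' @param path a dictionary file; default is the packaged curated list.
#' @return A named integer vector (names = lower-cased word forms), class
#'   `homophone_dict`.
#' @export
#' @examples
#' d <- homophone_dict()
#' unname(d["ate"])  # 8
homophone_dict <- function(path = system.file("extdata", "homophones.tsv",
                                              package = "dintest")) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed dictionary line(s): ", lines[bad][1], call. = FALSE)
  words <- tolower(vapply(parts, `[[`, character(1), 1L))
  digits <- as.integer(vapply(parts, `[[`, character(1), 2L))
  if (any(is.na(digits) | digits < 0L | digits > 9L)) {
    stop("dictionary digits must be 0-9", call. = FALSE)
  }
  # canonical forms always resolve
  canonical <- stats::setNames(
    rep(0:9, 2L),
    c(c("zero", "one", "two", "three", "four", "five", "six", "seven",
        "eight", "nine"), as.character(0:9))
  )
  entries <- c(canonical, stats::setNames(digits, words))
  entries <- entries[!duplicated(names(entries))]   # first (canonical) wins
  conflict <- tapply(c(canonical, stats::setNames(digits, words)),
                     names(c(canonical, stats::setNames(digits, words))),
                     function(v) length(unique(v)) > 1L)
  if (any(conflict)) {
    stop("word(s) mapped to two digits: ",
         paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)
  }
  structure(entries, class = "homophone_dict")
}

#' Normalize a free-text transcript into digits
#'
#' Lower-cases the transcript, strips punctuation, splits on whitespace and
#' resolves each token through the homophone dictionary. Tokens that do not
#' resolve are kept as data (`unresolved`), never raised as errors; the
#' resolved digits preserve token order.
#'
#' @param text transcript string (may be empty or `NA`).
#' @param dict a [homophone_dict()].
#' @return A list of class `parsed_response`: `digits` (integer vector, any
#'   length) and `unresolved` (character vector).
#' @export
#' @examples
#' normalize_transcript("one sex too")$digits  # 1 6 2
normalize_transcript <- function(text, dict = homophone_dict()) {
  if (is.null(text) || length(text) == 0L || is.na(text)) text <- ""
  clean <- gsub("[^a-z0-9]+", " ", tolower(text))
  tokens <- strsplit(trimws(clean), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  hit <- tokens %in% names(dict)
  structure(
    list(
      digits = unname(unclass(dict)[tokens[hit]]),
      unresolved = tokens[!hit]
    ),
    class = "parsed_response"
  )
}

#' Score a response against the presented triplet
#'
#' A response is correct only when it contains exactly three resolved digits
#' equal, position by position, to the presented triplet: order matters, a
#' short or over-long response is incorrect, and an empty transcript counts
#' as a (incorrect) no-response. There is no subsequence matching.
#'
#' @param presented integer vector of the three presented digits.
#' @param response a [normalize_transcript()] result, or a bare digit vector.
#' @return `TRUE`/`FALSE`.
#' @export
#' @examples
#' score_response(c(6, 1, 2), normalize_transcript("one six two"))  # FALSE
#' score_response(c(6, 1, 2), c(6, 1, 2))                           # TRUE
score_response <- function(presented, response) {
  presented <- as.integer(presented)
  if (length(presented) != 3L || anyDuplicated(presented)) {
    stop("`presented` must be a triplet of distinct digits", call. = FALSE)
  }
  digits <- if (inherits(response, "parsed_response")) response$digits
            else as.integer(response)
  length(digits) == 3L && all(digits == presented)
}
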