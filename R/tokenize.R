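# Tokenizer registry. The default tokenizer is language-agnostic; a
# morphological analyser (e.g. Korean noun extraction) can be plugged in by
# registering a function with the same contract: character scalar in,
# character vector of tokens out.

.tokenizer_registry <- new.env(parent = emptyenv())

#' Register a tokenizer
#'
#' Tokenizers are looked up by name in [tokenize()] and everywhere a
#' `tokenizer` argument is accepted. A tokenizer takes one narrative string
#' and returns a character vector of tokens (possibly empty).
#'
#' @param name Single string naming the tokenizer.
#' @param fn Function of one argument implementing the contract.
#' @return `fn`, invisibly.
#' @export
register_tokenizer <- function(name, fn) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    rlang::abort("`name` must be a non-empty string.")
  }
  if (!is.function(fn)) rlang::abort("`fn` must be a function.")
  assign(name, fn, envir = .tokenizer_registry)
  invisible(fn)
}

#' Resolve a tokenizer by name or pass a function through
#'
#' @param tokenizer A tokenizer name registered via [register_tokenizer()]
#'   (the built-in is `"default"`), or a function.
#' @return A tokenizer function.
#' @export
get_tokenizer <- function(tokenizer = "default") {
  if (is.function(tokenizer)) return(tokenizer)
  if (!is.character(tokenizer) || length(tokenizer) != 1L) {
    rlang::abort("`tokenizer` must be a function or a single name.")
  }
  if (!exists(tokenizer, envir = .tokenizer_registry, inherits = FALSE)) {
    stopf("Unknown tokenizer '%s'; register it with register_tokenizer().",
          tokenizer)
  }
  get(tokenizer, envir = .tokenizer_registry, inherits = FALSE)
}

#' Default tokenizer: lowercase, split on non-word characters
#'
#' Lowercases, splits on runs of characters that are neither alphanumeric nor
#' underscore, then drops tokens shorter than two characters and tokens made
#' solely of digits. This is the loss-free inverse of the synthetic corpus
#' generator, which joins tokens with single spaces.
#'
#' @param text Single narrative string.
#' @return Character vector of tokens, in order of appearance.
#' @export
#' @examples
#' default_tokenizer("Fell on icy road")
#' default_tokenizer("A1 B2 !! cc 17")
default_tokenizer <- function(text) {
  if (is.na(text)) return(character())
  toks <- strsplit(tolower(text), "[^[:alnum:]_]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[nchar(toks) >= 2L & !grepl("^[0-9]+$", toks)]
}

register_tokenizer("default", default_tokenizer)

#' Tokenize one narrative
#'
#' @param text Single narrative string.
#' @inheritParams get_tokenizer
#' @return Character vector of tokens (empty for an empty narrative).
#' @export
tokenize <- function(text, tokenizer = "default") {
  if (!is.character(text) || length(text) != 1L) {
    rlang::abort("`text` must be a single string; use tokenize_all() for many.")
  }
  get_tokenizer(tokenizer)(text)
}

#' Tokenize many narratives
#'
#' @param texts Character vector of narratives.
#' @inheritParams get_tokenizer
#' @return List of character token vectors, one per narrative.
#' @export
tokenize_all <- function(texts, tokenizer = "default") {
  fn <- get_tokenizer(tokenizer)
  lapply(as.character(texts), fn)
}
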