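#' English Snowball (Porter2) stemming
#'
#' Reduces an English word to its root form, e.g. `"creatures"` becomes
#' `"creatur"`, so that inflectional variants of a dictionary term or a
#' query keyword all collapse onto one indexed form. This is the same
#' normalization applied to dictionary surface forms at compile time and to
#' article text at tagging/indexing time, which is what makes the two sides
#' meet.
#'
#' The implementation follows the published English Snowball algorithm
#' (Porter2): exceptional forms, R1/R2 regions (with the `gener`/`commun`/
#' `arsen` prefixes), steps 0 through 5 and the final y-restoration.
#'
#' @param token character vector of single lowercase words.
#' @return character vector of stems, same length as `token`.
#' @examples
#' stem_token("creatures")  # "creatur"
#' stem_token(c("kidneys", "diseases"))
#' @export
stem_token <- function(token) {
  stopifnot(is.character(token))
  vapply(token, p2_stem_word, character(1), USE.NAMES = FALSE)
}

.p2_vowels <- c("a", "e", "i", "o", "u", "y")
.p2_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.p2_li_endings <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.p2_exception1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.p2_exception2 <- c(
  "inning", "outing", "canning", "herring", "earring",
  "proceed", "exceed", "succeed"
)

p2_is_vowel <- function(ch) ch %in% .p2_vowels

# R1 = region after the first non-vowel following a vowel (with the special
# prefixes); R2 = same rule applied again inside R1. Returned as 1-based start
# positions (len + 1 when the region is empty).
p2_regions <- function(ls) {
  n <- length(ls)
  word <- paste(ls, collapse = "")
  r1 <- n + 1L
  for (pre in c("gener", "commun", "arsen")) {
    if (startsWith(word, pre)) {
      r1 <- nchar(pre) + 1L
      break
    }
  }
  if (r1 == n + 1L) {
    for (i in seq_len(max(0L, n - 1L))) {
      if (p2_is_vowel(ls[i]) && !p2_is_vowel(ls[i + 1L])) {
        r1 <- i + 2L
        break
      }
    }
  }
  r2 <- n + 1L
  if (r1 <= n) {
    for (i in seq(r1, length.out = max(0L, n - r1))) {
      if (p2_is_vowel(ls[i]) && !p2_is_vowel(ls[i + 1L])) {
        r2 <- i + 2L
        break
      }
    }
  }
  c(r1 = r1, r2 = r2)
}

# TRUE when the word ends in a short syllable: non-vowel, vowel, non-vowel
# (not w/x/Y), or a vowel followed by a non-vowel at the start of the word.
p2_ends_short_syllable <- function(ls) {
  n <- length(ls)
  if (n == 2L) {
    return(p2_is_vowel(ls[1L]) && !p2_is_vowel(ls[2L]))
  }
  if (n >= 3L) {
    return(!p2_is_vowel(ls[n - 2L]) && p2_is_vowel(ls[n - 1L]) &&
             !p2_is_vowel(ls[n]) && !ls[n] %in% c("w", "x", "Y"))
  }
  FALSE
}

p2_ends <- function(ls, suffix) {
  n <- length(ls)
  k <- nchar(suffix)
  n >= k && paste(ls[(n - k + 1L):n], collapse = "") == suffix
}

# suffix lies entirely within the region starting at r
p2_in_region <- function(ls, suffix, r) {
  length(ls) - nchar(suffix) + 1L >= r
}

p2_stem_word <- function(word) {
  if (is.na(word)) return(NA_character_)
  if (startsWith(word, "'")) word <- substring(word, 2L)
  if (nchar(word) <= 2L) return(word)
  hit <- .p2_exception1[word]
  if (!is.na(hit)) return(unname(hit))

  ls <- strsplit(word, "", fixed = TRUE)[[1L]]

  # mark consonant y's as Y so they are not treated as vowels
  if (ls[1L] == "y") ls[1L] <- "Y"
  if (length(ls) > 1L) {
    for (i in 2:length(ls)) {
      if (ls[i] == "y" && p2_is_vowel(ls[i - 1L])) ls[i] <- "Y"
    }
  }

  reg <- p2_regions(ls)
  r1 <- reg[["r1"]]
  r2 <- reg[["r2"]]

  # step 0: trailing apostrophe forms
  for (suf in c("'s'", "'s", "'")) {
    if (p2_ends(ls, suf)) {
      ls <- ls[seq_len(length(ls) - nchar(suf))]
      break
    }
  }

  # step 1a
  if (p2_ends(ls, "sses")) {
    ls <- c(ls[seq_len(length(ls) - 4L)], "s", "s")
  } else if (p2_ends(ls, "ied") || p2_ends(ls, "ies")) {
    stem_len <- length(ls) - 3L
    ls <- ls[seq_len(stem_len)]
    ls <- if (stem_len > 1L) c(ls, "i") else c(ls, "i", "e")
  } else if (p2_ends(ls, "us") || p2_ends(ls, "ss")) {
    # leave alone
  } else if (p2_ends(ls, "s")) {
    n <- length(ls)
    if (n >= 3L && any(vapply(ls[seq_len(n - 2L)], p2_is_vowel, logical(1)))) {
      ls <- ls[seq_len(n - 1L)]
    }
  }

  if (paste(ls, collapse = "") %in% .p2_exception2) {
    return(paste(gsub("Y", "y", ls, fixed = TRUE), collapse = ""))
  }

  # step 1b
  if (p2_ends(ls, "eedly") || p2_ends(ls, "eed")) {
    suf <- if (p2_ends(ls, "eedly")) "eedly" else "eed"
    if (p2_in_region(ls, suf, r1)) {
      ls <- c(ls[seq_len(length(ls) - nchar(suf))], "e", "e")
    }
  } else {
    suf <- NULL
    for (s in c("ingly", "edly", "ing", "ed")) {
      if (p2_ends(ls, s)) { suf <- s; break }
    }
    if (!is.null(suf)) {
      stem <- ls[seq_len(length(ls) - nchar(suf))]
      if (any(vapply(stem, p2_is_vowel, logical(1)))) {
        ls <- stem
        tail2 <- if (length(ls) >= 2L) paste(ls[(length(ls) - 1L):length(ls)], collapse = "") else ""
        if (tail2 %in% c("at", "bl", "iz")) {
          ls <- c(ls, "e")
        } else if (tail2 %in% .p2_doubles) {
          ls <- ls[seq_len(length(ls) - 1L)]
        } else if (r1 > length(ls) && p2_ends_short_syllable(ls)) {
          ls <- c(ls, "e")
        }
      }
    }
  }

  # step 1c: y -> i after a non-vowel that is not the first letter
  n <- length(ls)
  if (n > 2L && ls[n] %in% c("y", "Y") && !p2_is_vowel(ls[n - 1L])) {
    ls[n] <- "i"
  }

  # step 2 (longest suffix; act only when in R1)
  step2 <- list(
    c("ization", "ize"), c("ational", "ate"), c("fulness", "ful"),
    c("ousness", "ous"), c("iveness", "ive"), c("tional", "tion"),
    c("biliti", "ble"), c("lessli", "less"), c("entli", "ent"),
    c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
    c("ousli", "ous"), c("iviti", "ive"), c("fulli", "ful"),
    c("enci", "ence"), c("anci", "ance"), c("abli", "able"),
    c("izer", "ize"), c("ator", "ate"), c("alli", "al"),
    c("bli", "ble"), c("ogi", "og"), c("li", "")
  )
  for (rule in step2) {
    suf <- rule[1L]
    if (p2_ends(ls, suf)) {
      if (p2_in_region(ls, suf, r1)) {
        keep <- length(ls) - nchar(suf)
        prev <- if (keep >= 1L) ls[keep] else ""
        if (suf == "ogi") {
          if (prev == "l") ls <- c(ls[seq_len(keep)], "o", "g")
        } else if (suf == "li") {
          if (prev %in% .p2_li_endings) ls <- ls[seq_len(keep)]
        } else {
          ls <- c(ls[seq_len(keep)], strsplit(rule[2L], "")[[1L]])
        }
      }
      break
    }
  }

  # step 3 (in R1; "ative" additionally requires R2)
  step3 <- list(
    c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
    c("icate", "ic"), c("iciti", "ic"), c("ative", ""),
    c("ical", "ic"), c("ness", ""), c("ful", "")
  )
  for (rule in step3) {
    suf <- rule[1L]
    if (p2_ends(ls, suf)) {
      if (p2_in_region(ls, suf, r1)) {
        if (suf == "ative" && !p2_in_region(ls, suf, r2)) break
        keep <- length(ls) - nchar(suf)
        ls <- c(ls[seq_len(keep)],
                if (nchar(rule[2L])) strsplit(rule[2L], "")[[1L]] else character(0))
      }
      break
    }
  }

  # step 4 (in R2)
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment",
             "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
             "al", "er", "ic")
  for (suf in step4) {
    if (p2_ends(ls, suf)) {
      if (p2_in_region(ls, suf, r2)) {
        keep <- length(ls) - nchar(suf)
        prev <- if (keep >= 1L) ls[keep] else ""
        if (suf != "ion" || prev %in% c("s", "t")) {
          ls <- ls[seq_len(keep)]
        }
      }
      break
    }
  }

  # step 5
  n <- length(ls)
  if (n >= 1L && ls[n] == "e") {
    in_r2 <- n >= r2
    in_r1 <- n >= r1
    if (in_r2 || (in_r1 && !p2_ends_short_syllable(ls[seq_len(n - 1L)]))) {
      ls <- ls[seq_len(n - 1L)]
    }
  } else if (n >= 2L && ls[n] == "l" && ls[n - 1L] == "l" && n >= r2) {
    ls <- ls[seq_len(n - 1L)]
  }

  paste(gsub("Y", "y", ls, fixed = TRUE), collapse = "")
}
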