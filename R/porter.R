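# Porter stemmer, original 1980 algorithm.
#
# Used only for words inside dependency relations (the "stemmed grammar
# relations" feature toggle); n-gram and substring features are never stemmed.
# Tokens containing non-letters (digits, hyphens) and words shorter than three
# letters are returned unchanged.

porter_vowels <- c("a", "e", "i", "o", "u")

# TRUE where a letter acts as a consonant; y is a consonant unless preceded by
# one (so "y" in "syzygy" alternates).
porter_cons_flags <- function(chars) {
  n <- length(chars)
  flags <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    flags[i] <- if (ch %in% porter_vowels) {
      FALSE
    } else if (ch == "y") {
      if (i == 1) TRUE else !flags[i - 1]
    } else {
      TRUE
    }
  }
  flags
}

# The measure m of a stem: number of vowel-consonant sequences [C](VC)^m[V].
porter_measure <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (length(ch) == 0) {
    return(0L)
  }
  runs <- rle(porter_cons_flags(ch))$values
  sum(runs[-1] & !runs[-length(runs)])
}

porter_has_vowel <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  length(ch) > 0 && any(!porter_cons_flags(ch))
}

porter_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2 || substr(stem, n - 1, n - 1) != substr(stem, n, n)) {
    return(FALSE)
  }
  porter_cons_flags(strsplit(stem, "", fixed = TRUE)[[1]])[n]
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not w/x/y.
porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3) {
    return(FALSE)
  }
  f <- porter_cons_flags(strsplit(stem, "", fixed = TRUE)[[1]])
  f[n - 2] && !f[n - 1] && f[n] &&
    !(substr(stem, n, n) %in% c("w", "x", "y"))
}

# Longest-matching-suffix rule application: once a suffix matches, its
# condition decides and no shorter suffix is tried.
porter_rule_step <- function(w, suffixes, replacements, min_m,
                             extra_cond = NULL) {
  ord <- order(-nchar(suffixes))
  for (k in ord) {
    suf <- suffixes[k]
    if (endsWith(w, suf)) {
      stem <- substr(w, 1, nchar(w) - nchar(suf))
      ok <- porter_measure(stem) > min_m
      if (ok && !is.null(extra_cond)) {
        ok <- extra_cond(stem, suf)
      }
      if (ok) {
        return(paste0(stem, replacements[k]))
      }
      return(w)
    }
  }
  w
}

porter_step1a <- function(w) {
  if (endsWith(w, "sses")) {
    sub("sses$", "ss", w)
  } else if (endsWith(w, "ies")) {
    sub("ies$", "i", w)
  } else if (endsWith(w, "ss")) {
    w
  } else if (endsWith(w, "s")) {
    sub("s$", "", w)
  } else {
    w
  }
}

porter_step1b <- function(w) {
  if (endsWith(w, "eed")) {
    stem <- sub("eed$", "", w)
    return(if (porter_measure(stem) > 0) paste0(stem, "ee") else w)
  }
  applied <- FALSE
  if (endsWith(w, "ed")) {
    stem <- sub("ed$", "", w)
    if (porter_has_vowel(stem)) {
      w <- stem
      applied <- TRUE
    }
  } else if (endsWith(w, "ing")) {
    stem <- sub("ing$", "", w)
    if (porter_has_vowel(stem)) {
      w <- stem
      applied <- TRUE
    }
  }
  if (applied) {
    last <- substr(w, nchar(w), nchar(w))
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porter_double_cons(w) && !(last %in% c("l", "s", "z"))) {
      w <- substr(w, 1, nchar(w) - 1)
    } else if (porter_measure(w) == 1 && porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

porter_step1c <- function(w) {
  if (endsWith(w, "y") && porter_has_vowel(substr(w, 1, nchar(w) - 1))) {
    sub("y$", "i", w)
  } else {
    w
  }
}

porter_step2 <- function(w) {
  porter_rule_step(
    w,
    c("ational", "tional", "enci", "anci", "izer", "abli", "alli", "entli",
      "eli", "ousli", "ization", "ation", "ator", "alism", "iveness",
      "fulness", "ousness", "aliti", "iviti", "biliti"),
    c("ate", "tion", "ence", "ance", "ize", "able", "al", "ent",
      "e", "ous", "ize", "ate", "ate", "al", "ive",
      "ful", "ous", "al", "ive", "ble"),
    min_m = 0
  )
}

porter_step3 <- function(w) {
  porter_rule_step(
    w,
    c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    c("ic", "", "al", "ic", "ic", "", ""),
    min_m = 0
  )
}

porter_step4 <- function(w) {
  porter_rule_step(
    w,
    c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
      "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"),
    rep("", 19),
    min_m = 1,
    extra_cond = function(stem, suf) {
      if (suf != "ion") {
        return(TRUE)
      }
      endsWith(stem, "s") || endsWith(stem, "t")
    }
  )
}

porter_step5a <- function(w) {
  if (!endsWith(w, "e")) {
    return(w)
  }
  stem <- substr(w, 1, nchar(w) - 1)
  m <- porter_measure(stem)
  if (m > 1 || (m == 1 && !porter_cvc(stem))) stem else w
}

porter_step5b <- function(w) {
  if (porter_measure(w) > 1 && porter_double_cons(w) && endsWith(w, "l")) {
    substr(w, 1, nchar(w) - 1)
  } else {
    w
  }
}

porter_stem_word <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2 || grepl("[^a-z]", w)) {
    return(w)
  }
  w <- porter_step1a(w)
  w <- porter_step1b(w)
  w <- porter_step1c(w)
  w <- porter_step2(w)
  w <- porter_step3(w)
  w <- porter_step4(w)
  w <- porter_step5a(w)
  porter_step5b(w)
}

#' Porter stem of each word
#'
#' The original Porter (1980) suffix-stripping algorithm. Words shorter than
#' three letters or containing non-letter characters (digits, hyphens) are
#' returned unchanged, so gene-like tokens such as `"p53"` survive intact.
#'
#' @param words Character vector.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("binds", "binding", "interactions", "phosphorylated"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}
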