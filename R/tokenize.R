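# Lexer for the static subset of Python the analyzer understands.
#
# The analyzer never executes code; it needs only imports, dotted call
# sites, keyword arguments, attribute assignments and os.environ accesses,
# so the lexer produces a flat token stream with bracket-aware logical
# newlines rather than a full grammar. Strings, comments and line
# continuations are consumed correctly so they can never masquerade as code.

.py_token_pattern <- paste0(
  "(?s)",
  "[rRbBuUfF]{0,2}(?:'{3}.*?'{3}|\"{3}.*?\"{3})",                # triple-quoted string
  "|[rRbBuUfF]{0,2}'(?:\\\\.|[^'\\\\\n])*'",                     # single-quoted string
  "|[rRbBuUfF]{0,2}\"(?:\\\\.|[^\"\\\\\n])*\"",                  # double-quoted string
  "|#[^\n]*",                                                    # comment
  "|[A-Za-z_][A-Za-z0-9_]*",                                     # name / keyword
  "|(?:[0-9][0-9_]*\\.?[0-9_]*|\\.[0-9][0-9_]*)(?:[eE][+-]?[0-9]+)?[jJ]?", # number
  "|\\\\\n",                                                     # explicit continuation
  "|\n",
  "|//=|\\*\\*=|<<=|>>=",
  "|==|!=|<=|>=|->|\\*\\*|//|<<|>>|:=|\\+=|-=|\\*=|/=|%=|&=|\\|=|\\^=|@=",
  "|[()\\[\\]{}.,:;=+\\-*/%&|^~<>@]",
  "|[ \t\r]+",
  "|."                                                           # anything else
)

.py_string_value <- function(tok) {
  body <- sub("^[rRbBuUfF]{0,2}", "", tok)
  if (grepl("^'''|^\"\"\"", body)) {
    substr(body, 4L, nchar(body) - 3L)
  } else {
    substr(body, 2L, nchar(body) - 1L)
  }
}

# Tokenize source text. Returns a data.frame with columns
# type (string|comment|name|number|newline|op|unknown), text, line, col
# (1-based lines, 0-based columns), plus attr "n_lines".
# Unterminated quotes and unbalanced brackets raise a detml_parse_error
# carrying the offending line number.
tokenize_python <- function(text) {
  text <- gsub("\r\n", "\n", text, fixed = TRUE)
  if (!nzchar(text)) {
    return(structure(
      data.frame(type = character(), text = character(),
                 line = integer(), col = integer(), stringsAsFactors = FALSE),
      n_lines = 0L))
  }
  m <- gregexpr(.py_token_pattern, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- substring(text, starts, starts + lens - 1L)

  nl_pos <- c(0L, gregexpr("\n", text, fixed = TRUE)[[1]])
  if (length(nl_pos) == 2L && nl_pos[2] == -1L) nl_pos <- 0L
  line_of <- findInterval(starts, nl_pos)           # 1-based line
  col_of <- starts - nl_pos[line_of] - 1L           # 0-based column

  first <- substr(toks, 1L, 1L)
  type <- character(length(toks))
  is_string <- grepl("^[rRbBuUfF]{0,2}['\"]", toks) & nchar(toks) > 1L &
    grepl("['\"]$", toks)
  type[is_string] <- "string"
  type[!is_string & first == "#"] <- "comment"
  type[!is_string & grepl("^[A-Za-z_]", toks)] <- "name"
  type[!is_string & grepl("^[0-9.]", toks) & grepl("[0-9]", toks)] <- "number"
  type[toks == "\n"] <- "newline"
  type[toks == "\\\n"] <- "continuation"
  ws <- grepl("^[ \t\r]+$", toks)
  type[ws] <- "ws"
  type[type == ""] <- "op"
  # "." alone is an op, not a number
  type[toks == "."] <- "op"

  # unterminated string: a bare quote survives as a 1-char op-class token
  bad <- which(first %in% c("'", "\"") & !is_string)
  if (length(bad)) {
    detml_stop("unterminated string literal at line %d", line_of[bad[1]],
               class = "detml_parse_error")
  }

  keep <- !(type %in% c("comment", "ws", "continuation"))
  out <- data.frame(type = type[keep], text = toks[keep],
                    line = line_of[keep], col = col_of[keep],
                    stringsAsFactors = FALSE)

  # bracket depth: suppress newlines inside brackets, check balance
  depth <- 0L
  drop <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    tk <- out$text[i]
    if (out$type[i] == "op") {
      if (tk %in% c("(", "[", "{")) depth <- depth + 1L
      else if (tk %in% c(")", "]", "}")) {
        depth <- depth - 1L
        if (depth < 0L) {
          detml_stop("unbalanced '%s' at line %d", tk, out$line[i],
                     class = "detml_parse_error")
        }
      }
    } else if (out$type[i] == "newline" && depth > 0L) {
      drop[i] <- TRUE
    }
  }
  if (depth > 0L) {
    detml_stop("unbalanced brackets at end of file (depth %d)", depth,
               class = "detml_parse_error")
  }
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_lines") <- length(nl_pos) - 1L + 1L
  out
}
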