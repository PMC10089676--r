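#' Parse Python source into a static syntax model
#'
#' Builds the static model the lint rules are evaluated against: an alias
#' table mapping local names to canonical qualified names (from `import` and
#' `import ... as ...` statements), every statically resolvable call site,
#' keyword arguments with constant values, attribute assignments with
#' constant values, and `os.environ` reads/writes.
#'
#' The analysis is purely static and single-file: dynamic constructs
#' (computed attribute access, `exec`, dict-literal configuration keys) are
#' not resolved and never produce findings.
#'
#' @param text Python source code as a single string (UTF-8).
#' @param source_id Identifier recorded in the model and in findings;
#'   defaults to `"<memory>"`.
#' @return An object of class `detml_syntax_model`: a list with elements
#'   `source_id`, `aliases` (named character vector), `import_roots`,
#'   `calls`, `kwargs`, `env_refs`, `assignments` (data.frames), `n_lines`.
#' @examples
#' m <- parse_python_source("import numpy as np\nnp.random.seed(0)")
#' m$calls$qualified
#' @export
parse_python_source <- function(text, source_id = "<memory>") {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_python(text)
  n <- nrow(toks)

  aliases <- character(0)
  import_roots <- character(0)
  calls <- list()
  kwargs <- list()
  env_refs <- list()
  assigns <- list()

  # ---- pass 1: imports (statement-level) -----------------------------------
  stmt_start <- c(TRUE, toks$type[-n] == "newline" | toks$text[-n] == ";")
  if (n == 0L) stmt_start <- logical(0)
  i <- 1L
  while (i <= n) {
    if (stmt_start[i] && toks$type[i] == "name" &&
        toks$text[i] %in% c("import", "from")) {
      j <- i + 1L
      end <- j
      while (end <= n && toks$type[end] != "newline" && toks$text[end] != ";") {
        end <- end + 1L
      }
      stmt <- toks[j:(end - 1L), , drop = FALSE]
      if (toks$text[i] == "import") {
        parsed <- .parse_import_clause(stmt)
      } else {
        parsed <- .parse_from_clause(stmt)
      }
      aliases[names(parsed$aliases)] <- parsed$aliases
      import_roots <- union(import_roots, parsed$roots)
      i <- end
    }
    i <- i + 1L
  }

  resolve <- function(chain) {
    head <- chain[1L]
    if (head %in% names(aliases)) {
      paste(c(aliases[[head]], chain[-1L]), collapse = ".")
    } else {
      paste(chain, collapse = ".")
    }
  }

  # ---- pass 2: dotted chains, calls, kwargs, assignments, environ ----------
  kw <- c("and", "or", "not", "if", "else", "elif", "for", "while", "def",
          "class", "return", "import", "from", "as", "in", "is", "lambda",
          "with", "try", "except", "finally", "raise", "assert", "yield",
          "global", "nonlocal", "del", "pass", "break", "continue", "await",
          "async", "True", "False", "None", "print")
  const_value <- function(k) {
    if (k > n) return(NULL)
    if (toks$type[k] == "string") return(.py_string_value(toks$text[k]))
    if (toks$type[k] == "number") {
      return(suppressWarnings(as.numeric(gsub("[_jJ]", "", toks$text[k]))))
    }
    if (toks$type[k] == "name") {
      if (toks$text[k] == "True") return(TRUE)
      if (toks$text[k] == "False") return(FALSE)
      if (toks$text[k] == "None") return(NA)
    }
    NULL
  }

  i <- 1L
  while (i <= n) {
    if (toks$type[i] == "name" && !(toks$text[i] %in% c("import", "from", "as")) &&
        (i == 1L || toks$text[i - 1L] != ".") &&
        (i == 1L || !(toks$type[i - 1L] == "name" &&
                      toks$text[i - 1L] %in% c("def", "class")))) {
      chain <- toks$text[i]
      j <- i + 1L
      while (j + 1L <= n && toks$text[j] == "." && toks$type[j + 1L] == "name") {
        chain <- c(chain, toks$text[j + 1L])
        j <- j + 2L
      }
      qualified <- resolve(chain)
      line <- toks$line[i]; col <- toks$col[i]

      if (j <= n && toks$text[j] == "(" && !(chain[1L] %in% kw)) {
        # call site; collect first positional string arg and keyword args
        depth <- 1L; k <- j + 1L
        first_arg <- const_value(k)
        prev_text <- "("
        while (k <= n && depth > 0L) {
          tk <- toks$text[k]
          if (toks$type[k] == "op") {
            if (tk %in% c("(", "[", "{")) depth <- depth + 1L
            if (tk %in% c(")", "]", "}")) depth <- depth - 1L
          }
          if (depth == 1L && toks$type[k] == "name" &&
              k + 1L <= n && toks$text[k + 1L] == "=" &&
              prev_text %in% c("(", ",")) {
            kwargs[[length(kwargs) + 1L]] <- list(
              name = tk, call = qualified,
              value = const_value(k + 2L), line = toks$line[k])
          }
          prev_text <- tk
          k <- k + 1L
        }
        fa_truthy <- if (is.null(first_arg)) NA
        else if (is.logical(first_arg)) first_arg[1]
        else if (is.numeric(first_arg)) first_arg != 0
        else if (is.character(first_arg)) nzchar(first_arg)
        else NA
        calls[[length(calls) + 1L]] <- list(
          qualified = qualified, line = line, col = col,
          first_arg = if (is.character(first_arg)) first_arg else NA_character_,
          first_arg_truthy = fa_truthy)

        # os.environ.* call forms
        if (qualified %in% c("os.environ.setdefault", "os.putenv") &&
            is.character(first_arg)) {
          env_refs[[length(env_refs) + 1L]] <-
            list(name = first_arg, access = "write", line = line)
        } else if (qualified %in% c("os.environ.get", "os.getenv") &&
                   is.character(first_arg)) {
          env_refs[[length(env_refs) + 1L]] <-
            list(name = first_arg, access = "read", line = line)
        }
        i <- j
      } else if (length(chain) >= 2L && qualified == "os.environ" &&
                 j + 2L <= n && toks$text[j] == "[" &&
                 toks$type[j + 1L] == "string" && toks$text[j + 2L] == "]") {
        var <- .py_string_value(toks$text[j + 1L])
        is_write <- j + 3L <= n && toks$text[j + 3L] == "=" &&
          toks$type[j + 3L] == "op"
        env_refs[[length(env_refs) + 1L]] <-
          list(name = var, access = if (is_write) "write" else "read",
               line = line)
        i <- j + 2L
      } else if (length(chain) >= 2L && j <= n && toks$text[j] == "=" &&
                 toks$type[j] == "op") {
        assigns[[length(assigns) + 1L]] <- list(
          target = qualified, value = const_value(j + 1L), line = line)
        i <- j
      } else {
        i <- j - 1L
      }
    }
    i <- i + 1L
  }

  to_df <- function(lst, cols) {
    if (!length(lst)) {
      return(as.data.frame(cols, stringsAsFactors = FALSE)[0, , drop = FALSE])
    }
    out <- cols
    for (nm in names(cols)) {
      vals <- lapply(lst, function(x) x[[nm]])
      if (is.list(cols[[nm]])) {
        out[[nm]] <- vals
      } else {
        vals[vapply(vals, is.null, logical(1))] <- list(cols[[nm]][0][NA])
        out[[nm]] <- unlist(lapply(vals, function(v) {
          v <- v[1]
          storage.mode(v) <- storage.mode(cols[[nm]])
          v
        }))
      }
    }
    structure(out, class = "data.frame", row.names = seq_along(lst))
  }

  model <- list(
    source_id = source_id,
    aliases = aliases,
    import_roots = import_roots,
    calls = to_df(calls, list(qualified = character(), line = integer(),
                              col = integer(), first_arg = character(),
                              first_arg_truthy = logical())),
    kwargs = to_df(kwargs, list(name = character(), call = character(),
                                value = list(), line = integer())),
    env_refs = to_df(env_refs, list(name = character(), access = character(),
                                    line = integer())),
    assignments = to_df(assigns, list(target = character(), value = list(),
                                      line = integer())),
    n_lines = attr(toks, "n_lines") %||% 0L
  )
  class(model) <- "detml_syntax_model"
  model
}

# "import a.b.c as x, d.e" -> aliases + roots
.parse_import_clause <- function(stmt) {
  aliases <- character(0); roots <- character(0)
  parts <- .split_on_commas(stmt)
  for (p in parts) {
    nm <- p$text[p$type == "name" | p$text == "."]
    as_idx <- which(p$text == "as" & p$type == "name")
    if (length(as_idx)) {
      mod <- paste(p$text[seq_len(as_idx - 1L)], collapse = "")
      alias <- p$text[as_idx + 1L]
      aliases[alias] <- mod
    } else {
      mod <- paste(p$text, collapse = "")
      aliases[strsplit(mod, ".", fixed = TRUE)[[1]][1]] <-
        strsplit(mod, ".", fixed = TRUE)[[1]][1]
    }
    roots <- union(roots, strsplit(mod, ".", fixed = TRUE)[[1]][1])
  }
  list(aliases = aliases, roots = roots)
}

# "from a.b import c as d, e" -> aliases c/d -> a.b.c etc.
.parse_from_clause <- function(stmt) {
  aliases <- character(0); roots <- character(0)
  imp <- which(stmt$text == "import" & stmt$type == "name")[1]
  if (is.na(imp)) return(list(aliases = aliases, roots = roots))
  modtoks <- stmt[seq_len(imp - 1L), , drop = FALSE]
  mod <- paste(modtoks$text, collapse = "")
  if (grepl("^\\.", mod)) return(list(aliases = aliases, roots = roots)) # relative
  roots <- strsplit(mod, ".", fixed = TRUE)[[1]][1]
  rest <- stmt[-seq_len(imp), , drop = FALSE]
  if (any(rest$text == "*")) return(list(aliases = aliases, roots = roots))
  for (p in .split_on_commas(rest)) {
    nms <- p$text[p$type == "name"]
    if (!length(nms)) next
    as_idx <- which(nms == "as")
    if (length(as_idx)) {
      aliases[nms[as_idx + 1L]] <- paste(mod, nms[1L], sep = ".")
    } else {
      aliases[nms[1L]] <- paste(mod, nms[1L], sep = ".")
    }
  }
  list(aliases = aliases, roots = roots)
}

.split_on_commas <- function(stmt) {
  if (!nrow(stmt)) return(list())
  grp <- cumsum(stmt$text == ",")
  keep <- stmt$text != "," & !(stmt$text %in% c("(", ")"))
  lapply(split(seq_len(nrow(stmt))[keep], grp[keep]),
         function(ix) stmt[ix, , drop = FALSE])
}

#' @export
print.detml_syntax_model <- function(x, ...) {
  cat("<detml syntax model> ", x$source_id, "\n", sep = "")
  cat("  imports:", paste(x$import_roots, collapse = ", "), "\n")
  cat("  call sites:", nrow(x$calls),
      " env refs:", nrow(x$env_refs),
      " assignments:", nrow(x$assignments), "\n")
  invisible(x)
}
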