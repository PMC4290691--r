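#' Parse a CTL formula
#'
#' Grammar (precedence low to high): implication \code{->} (right
#' associative), disjunction \code{|}, conjunction \code{&}, negation
#' \code{!}, then the temporal prefixes \code{EX AX EF AF EG AG} which
#' bind the immediately following formula, and bracketed until forms
#' \code{E[f U g]} / \code{A[f U g]}.  Atoms compare a node against a
#' constant with \code{=}, \code{>=} or \code{<=}; for Boolean nodes
#' \code{True}/\code{False} are accepted as sugar for 1/0.  Bare
#' \code{True}/\code{False} are constants.
#'
#' @param text formula string.
#' @param net the [network()] atoms are resolved against.
#' @return An abstract syntax tree of class \code{qmc_ctl}.
#' @examples
#' net <- network(list(node_spec("ASK1"), node_spec("Abeta"),
#'                     node_spec("Alzheimer", kind = "output")))
#' f <- parse_ctl("AG (ASK1 = 2 -> AF (Abeta >= 1 & Alzheimer = True))", net)
#' format(f)
#' @export
parse_ctl <- function(text, net) {
  toks <- ctl_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$net <- net
  ast <- p_implies(st)
  tk <- peek_tok(st)
  if (tk$type != "eof") {
    stop("syntax error at position ", tk$at, ": unexpected '", tk$text, "'")
  }
  structure(ast, class = "qmc_ctl", text = text)
}

ctl_tokens <- function(text) {
  pat <- paste0(
    "(?<ws>\\s+)|",
    "(?<op>->|>=|<=|=|!|&|\\||\\(|\\)|\\[|\\])|",
    "(?<num>[0-9]+)|",
    "(?<id>[A-Za-z_][A-Za-z0-9_]*)"
  )
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    m <- regexpr(pat, substr(text, i, n), perl = TRUE)
    if (m != 1L) {
      stop("syntax error at position ", i, ": unexpected character '",
           substr(text, i, i), "'")
    }
    len <- attr(m, "match.length")
    piece <- substr(text, i, i + len - 1L)
    type <- if (grepl("^\\s", piece)) "ws"
            else if (grepl("^[0-9]", piece)) "num"
            else if (grepl("^[A-Za-z_]", piece)) "id"
            else "op"
    if (type != "ws") toks[[length(toks) + 1L]] <- list(type = type, text = piece, at = i)
    i <- i + len
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", text = "<end>", at = n + 1L)
  toks
}

peek_tok <- function(st) st$toks[[st$pos]]
next_tok <- function(st) {
  tk <- st$toks[[st$pos]]
  st$pos <- st$pos + 1L
  tk
}
expect_tok <- function(st, text) {
  tk <- next_tok(st)
  if (!identical(tk$text, text)) {
    stop("syntax error at position ", tk$at, ": expected '", text,
         "' but found '", tk$text, "'")
  }
  tk
}

p_implies <- function(st) {
  lhs <- p_or(st)
  if (peek_tok(st)$text == "->") {
    next_tok(st)
    rhs <- p_implies(st)  # right associative
    return(list(type = "implies", lhs = lhs, rhs = rhs))
  }
  lhs
}

p_or <- function(st) {
  lhs <- p_and(st)
  while (peek_tok(st)$text == "|") {
    next_tok(st)
    lhs <- list(type = "or", lhs = lhs, rhs = p_and(st))
  }
  lhs
}

p_and <- function(st) {
  lhs <- p_unary(st)
  while (peek_tok(st)$text == "&") {
    next_tok(st)
    lhs <- list(type = "and", lhs = lhs, rhs = p_unary(st))
  }
  lhs
}

temporal_prefixes <- c("EX", "AX", "EF", "AF", "EG", "AG")

p_unary <- function(st) {
  tk <- peek_tok(st)
  if (tk$text == "!") {
    next_tok(st)
    return(list(type = "not", sub = p_unary(st)))
  }
  if (tk$type == "id" && tk$text %in% temporal_prefixes) {
    next_tok(st)
    return(list(type = tk$text, sub = p_unary(st)))
  }
  if (tk$type == "id" && tk$text %in% c("E", "A") &&
      st$toks[[st$pos + 1L]]$text == "[") {
    quant <- next_tok(st)$text
    expect_tok(st, "[")
    lhs <- p_implies(st)
    utok <- next_tok(st)
    if (!(utok$type == "id" && utok$text == "U")) {
      stop("syntax error at position ", utok$at, ": expected 'U' in ", quant,
           "[ ... U ... ]")
    }
    rhs <- p_implies(st)
    expect_tok(st, "]")
    return(list(type = paste0(quant, "U"), lhs = lhs, rhs = rhs))
  }
  p_primary(st)
}

p_primary <- function(st) {
  tk <- next_tok(st)
  if (tk$text == "(") {
    inner <- p_implies(st)
    expect_tok(st, ")")
    return(inner)
  }
  if (tk$type == "id" && tk$text %in% c("True", "False")) {
    return(list(type = "const", value = tk$text == "True"))
  }
  if (tk$type == "id") {
    nm <- tk$text
    nms <- node_names(st$net)
    if (!nm %in% nms) {
      stop("unknown node '", nm, "' at position ", tk$at)
    }
    cmp_tok <- next_tok(st)
    if (!cmp_tok$text %in% c("=", ">=", "<=")) {
      stop("syntax error at position ", cmp_tok$at,
           ": expected comparator after node '", nm, "'")
    }
    val_tok <- next_tok(st)
    lev <- node_levels(st$net)[[nm]]
    val <- if (val_tok$type == "num") {
      as.integer(val_tok$text)
    } else if (val_tok$type == "id" && val_tok$text %in% c("True", "False")) {
      if (lev != 2L) {
        stop("True/False used with non-Boolean node '", nm, "' at position ",
             val_tok$at)
      }
      if (val_tok$text == "True") 1L else 0L
    } else {
      stop("syntax error at position ", val_tok$at, ": expected a constant")
    }
    if (val < 0L || val > lev - 1L) {
      stop("constant ", val, " outside domain [0, ", lev - 1L, "] of node '",
           nm, "' at position ", val_tok$at)
    }
    return(list(type = "atom", node = nm, cmp = cmp_tok$text, value = val))
  }
  stop("syntax error at position ", tk$at, ": unexpected '", tk$text, "'")
}

#' @export
format.qmc_ctl <- function(x, ...) deparse_ctl(unclass(x))

#' @export
print.qmc_ctl <- function(x, ...) {
  cat("qmc_ctl:", format(x), "\n")
  invisible(x)
}

deparse_ctl <- function(f) {
  switch(f$type,
    const = if (f$value) "True" else "False",
    atom = paste(f$node, f$cmp, f$value),
    not = paste0("!", wrap_ctl(f$sub)),
    and = paste(wrap_ctl(f$lhs), "&", wrap_ctl(f$rhs)),
    or = paste(wrap_ctl(f$lhs), "|", wrap_ctl(f$rhs)),
    implies = paste(wrap_ctl(f$lhs), "->", wrap_ctl(f$rhs)),
    EU = paste0("E[", deparse_ctl(f$lhs), " U ", deparse_ctl(f$rhs), "]"),
    AU = paste0("A[", deparse_ctl(f$lhs), " U ", deparse_ctl(f$rhs), "]"),
    paste(f$type, wrap_ctl(f$sub))  # temporal prefix
  )
}

wrap_ctl <- function(f) {
  if (f$type %in% c("atom", "const", "not", "EU", "AU")) return(deparse_ctl(f))
  paste0("(", deparse_ctl(f), ")")
}

# All node names referenced by a formula's atoms.
ctl_atoms <- function(f) {
  if (f$type == "atom") return(f$node)
  kids <- f[names(f) %in% c("sub", "lhs", "rhs")]
  unique(unlist(lapply(kids, ctl_atoms)))
}

# Evaluate a propositional (temporal-free) formula at a single state.
# Used by trace replay checks; errors on temporal operators.
eval_prop <- function(f, state) {
  switch(f$type,
    const = f$value,
    atom = switch(f$cmp,
      "=" = state[[f$node]] == f$value,
      ">=" = state[[f$node]] >= f$value,
      "<=" = state[[f$node]] <= f$value),
    not = !eval_prop(f$sub, state),
    and = eval_prop(f$lhs, state) && eval_prop(f$rhs, state),
    or = eval_prop(f$lhs, state) || eval_prop(f$rhs, state),
    implies = !eval_prop(f$lhs, state) || eval_prop(f$rhs, state),
    stop("formula is not propositional: ", f$type)
  )
}
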