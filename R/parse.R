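# Parser for the plain-text power-law equation dialect.
#
# One equation per string: "X1. = a1*X100^-1 + ... - b1*X1" declares
# dX1/dt; "0 = 1 + X1^2*K1^-2 - X100" declares an algebraic constraint.
# `*` is multiplication, `^` is power, a leading or separating `-` starts a
# negative term.  Parenthesised sums are only meaningful for rational-form
# models destined for recast(); a GMA system must be sums of plain
# power-law terms.

dsd_tokenize <- function(text) {
  pat <- "([A-Za-z_$][A-Za-z0-9_]*)|([0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?)|([-+*^=()./])|(\\s+)|(.)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- substring(text, starts, starts + lens - 1)
  keep <- !grepl("^\\s+$", toks)
  toks <- toks[keep]; starts <- starts[keep]
  bad <- grepl("^[^A-Za-z0-9_$.+*^=()/-]$", toks)
  if (any(bad)) {
    stop(sprintf("syntax error: unexpected character '%s' at position %d",
                 toks[bad][1], starts[bad][1]), call. = FALSE)
  }
  list(tok = toks, pos = starts, i = 1L, text = text)
}

tk_peek <- function(st) if (st$i <= length(st$tok)) st$tok[st$i] else ""
tk_next <- function(st) { st$i <- st$i + 1L; st }
tk_expect <- function(st, what) {
  if (tk_peek(st) != what) {
    stop(sprintf("syntax error: expected '%s' at position %d in \"%s\"", what,
                 if (st$i <= length(st$pos)) st$pos[st$i] else nchar(st$text) + 1L,
                 st$text), call. = FALSE)
  }
  tk_next(st)
}
tk_is_name <- function(x) grepl("^[A-Za-z_$]", x)
tk_is_number <- function(x) grepl("^[0-9]", x)

# exponent := ['-'] NUMBER | '(' ['-'] NUMBER ['/' NUMBER] ')'
# returns c(num, den) of an exact rational
parse_exponent <- function(st) {
  neg <- 1
  paren <- FALSE
  if (tk_peek(st) == "(") { st <- tk_next(st); paren <- TRUE }
  if (tk_peek(st) == "-") { neg <- -1; st <- tk_next(st) }
  if (!tk_is_number(tk_peek(st))) {
    stop(sprintf("syntax error: expected numeric exponent at position %d in \"%s\"",
                 st$pos[st$i], st$text), call. = FALSE)
  }
  num <- tk_peek(st); st <- tk_next(st)
  den <- 1
  if (paren && tk_peek(st) == "/") {
    st <- tk_next(st)
    if (!tk_is_number(tk_peek(st))) {
      stop("syntax error: expected denominator after '/'", call. = FALSE)
    }
    den <- as.numeric(tk_peek(st)); st <- tk_next(st)
  }
  if (paren) st <- tk_expect(st, ")")
  r <- rat_from_numeric(matrix(as.numeric(num) / den))
  st$value <- c(num = neg * r$num[1, 1], den = r$den[1, 1])
  st
}

# atom := NAME | NUMBER | '(' sum ')'
parse_atom <- function(st) {
  t <- tk_peek(st)
  if (tk_is_name(t)) {
    st <- tk_next(st)
    st$value <- list(kind = "sym", value = t)
  } else if (tk_is_number(t)) {
    st <- tk_next(st)
    st$value <- list(kind = "num", value = as.numeric(t))
  } else if (t == "(") {
    st <- tk_next(st)
    st <- parse_sum(st)
    inner <- st$value
    st <- tk_expect(st, ")")
    st$value <- list(kind = "sum", value = inner)
  } else {
    stop(sprintf("syntax error: unexpected token '%s' at position %d in \"%s\"",
                 t, if (st$i <= length(st$pos)) st$pos[st$i] else nchar(st$text) + 1L,
                 st$text), call. = FALSE)
  }
  st
}

# factor := atom ['^' exponent]
parse_factor <- function(st) {
  st <- parse_atom(st)
  atom <- st$value
  expo <- c(num = 1, den = 1)
  if (tk_peek(st) == "^") {
    st <- tk_next(st)
    st <- parse_exponent(st)
    expo <- st$value
  }
  atom$expo <- expo
  st$value <- atom
  st
}

# term := factor ('*' factor)*
parse_term <- function(st) {
  factors <- list()
  repeat {
    st <- parse_factor(st)
    factors[[length(factors) + 1L]] <- st$value
    if (tk_peek(st) == "*") st <- tk_next(st) else break
  }
  st$value <- factors
  st
}

# sum := ['-'] term (('+'|'-') term)*
parse_sum <- function(st) {
  terms <- list()
  sign <- 1
  if (tk_peek(st) == "-") { sign <- -1; st <- tk_next(st) }
  repeat {
    st <- parse_term(st)
    terms[[length(terms) + 1L]] <- list(sign = sign, factors = st$value)
    t <- tk_peek(st)
    if (t == "+") { sign <- 1; st <- tk_next(st) }
    else if (t == "-") { sign <- -1; st <- tk_next(st) }
    else break
  }
  st$value <- terms
  st
}

# Parse one equation string into lhs kind/variable and structured terms.
parse_equation_string <- function(text) {
  st <- dsd_tokenize(text)
  t <- tk_peek(st)
  if (t == "0") {
    st <- tk_next(st)
    lhs_kind <- "constraint"; lhs <- NA_character_
  } else if (tk_is_name(t)) {
    st <- tk_next(st)
    st <- tk_expect(st, ".")
    lhs_kind <- "ode"; lhs <- t
  } else {
    stop(sprintf("syntax error: equation must start with a variable derivative or 0, got '%s' in \"%s\"",
                 t, text), call. = FALSE)
  }
  st <- tk_expect(st, "=")
  st <- parse_sum(st)
  if (st$i <= length(st$tok)) {
    stop(sprintf("syntax error: trailing token '%s' at position %d in \"%s\"",
                 tk_peek(st), st$pos[st$i], text), call. = FALSE)
  }
  list(lhs_kind = lhs_kind, lhs = lhs, terms = st$value, source = text)
}

# --- power-law term representation -----------------------------------------
# A power-law term is a numeric coefficient plus exact rational exponents per
# symbol, kept in first-appearance order: list(coef, en, ed) with en/ed named
# numerator/denominator vectors.

pl_new <- function(coef = 1) list(coef = coef, en = numeric(0), ed = numeric(0))

pl_mul_sym <- function(term, sym, expo) {
  if (sym %in% names(term$en)) {
    cur <- c(num = unname(term$en[[sym]]), den = unname(term$ed[[sym]]))
    num <- cur[["num"]] * expo[["den"]] + expo[["num"]] * cur[["den"]]
    den <- cur[["den"]] * expo[["den"]]
    g <- rat_gcd(num, den)
    term$en[[sym]] <- num / g
    term$ed[[sym]] <- den / g
    if (term$en[[sym]] == 0) {
      term$en <- term$en[names(term$en) != sym]
      term$ed <- term$ed[names(term$ed) != sym]
    }
  } else if (expo[["num"]] != 0) {
    term$en[[sym]] <- expo[["num"]]
    term$ed[[sym]] <- expo[["den"]]
  }
  term
}

pl_mul <- function(a, b) {
  a$coef <- a$coef * b$coef
  for (sym in names(b$en)) {
    a <- pl_mul_sym(a, sym, c(num = unname(b$en[[sym]]), den = unname(b$ed[[sym]])))
  }
  a
}

pl_exponent <- function(term, sym) {
  if (sym %in% names(term$en)) unname(term$en[[sym]] / term$ed[[sym]]) else 0
}

pl_exponents <- function(term, syms) {
  vapply(syms, function(s) pl_exponent(term, s), numeric(1))
}

pl_value <- function(term, point) {
  v <- term$coef
  for (sym in names(term$en)) {
    if (is.na(point[sym])) stop(sprintf("missing value for '%s'", sym), call. = FALSE)
    v <- v * unname(point[[sym]])^(term$en[[sym]] / term$ed[[sym]])
  }
  v
}

pl_to_string <- function(term) {
  parts <- character(0)
  if (term$coef != 1 || length(term$en) == 0) parts <- format(term$coef, digits = 15)
  for (sym in names(term$en)) {
    e_num <- term$en[[sym]]; e_den <- term$ed[[sym]]
    if (e_num == e_den) {
      parts <- c(parts, sym)
    } else if (e_den == 1) {
      parts <- c(parts, paste0(sym, "^", format(e_num, digits = 15)))
    } else {
      parts <- c(parts, paste0(sym, "^(", e_num, "/", e_den, ")"))
    }
  }
  paste(parts, collapse = "*")
}

# Convert a structured term (list of factors) into a plain power-law term.
# Sum factors are rejected: those belong to rational models (see recast()).
structured_to_powerlaw <- function(factors, where = "") {
  term <- pl_new()
  for (f in factors) {
    if (f$kind == "sum") {
      stop(paste0("unsupported form: parenthesised sum in a GMA term", where,
                  "; rational-form models must go through recast()"), call. = FALSE)
    }
    if (f$kind == "num") {
      term$coef <- term$coef * f$value^(f$expo[["num"]] / f$expo[["den"]])
    } else {
      term <- pl_mul_sym(term, f$value, f$expo)
    }
  }
  term
}

# Parse a power-law inequality such as "rho1 > 1", "X1 < Xr1" or
# "$X2_0 < $X2_1" into (lhs term, relation, rhs term).
parse_constraint_string <- function(text) {
  op <- regmatches(text, regexpr("[<>]=?", text))
  if (length(op) == 0) stop(sprintf("constraint \"%s\" must contain '<' or '>'", text), call. = FALSE)
  sides <- strsplit(text, "[<>]=?")[[1]]
  if (length(sides) != 2) stop(sprintf("constraint \"%s\" must have a single comparison", text), call. = FALSE)
  parse_side <- function(s) {
    st <- dsd_tokenize(s)
    st <- parse_term(st)
    if (st$i <= length(st$tok)) {
      stop(sprintf("syntax error: trailing token in constraint side \"%s\"", s), call. = FALSE)
    }
    structured_to_powerlaw(st$value, where = sprintf(" in constraint \"%s\"", text))
  }
  list(lhs = parse_side(sides[1]), op = substr(op, 1, 1), rhs = parse_side(sides[2]),
       source = text)
}
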