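# Parsing of Boolean gene-protein-reaction (GPR) rules and expansion to
# disjunctive normal form. OR joins isozymes, AND joins members of a complex.

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  leftover <- gsub(pat, "", text)
  leftover <- gsub("[[:space:]]", "", leftover)
  if (nzchar(leftover))
    stop_mri("unparseable gene rule: '", text, "'")
  toks
}

# Recursive-descent parse into a tree of lists:
#   list(op = "and"/"or", args = list(...)) or list(gene = "id")
gpr_parse <- function(text) {
  text <- trimws(text %||% "")
  if (!nzchar(text)) return(NULL)
  toks <- gpr_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop_mri("unparseable gene rule: '", text, "'")
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (!identical(peek(), ")"))
        stop_mri("unparseable gene rule (unbalanced parentheses): '", text, "'")
      advance()
      return(node)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or"))
      stop_mri("unparseable gene rule: '", text, "'")
    advance()
    list(gene = t)
  }

  node <- parse_expr()
  if (pos <= length(toks))
    stop_mri("unparseable gene rule: '", text, "'")
  node
}

# DNF expansion: returns a list of character vectors, each vector one
# conjunct (set of genes ANDed together). `cap` bounds the number of
# disjuncts; deeply nested rules abort rather than silently truncate.
gpr_dnf <- function(node, cap = 32L, rule_text = "") {
  if (is.null(node)) return(list())
  rec <- function(nd) {
    if (!is.null(nd$gene)) return(list(nd$gene))
    parts <- lapply(nd$args, rec)
    if (nd$op == "or") {
      out <- do.call(c, parts)
    } else {
      out <- list(character(0))
      for (p in parts) {
        out <- unlist(lapply(out, function(a)
          lapply(p, function(b) union(a, b))), recursive = FALSE)
        if (length(out) > cap)
          stop_mri("DNF expansion of rule '", rule_text, "' exceeds cap of ",
                   cap, " disjuncts")
      }
      out
    }
    if (length(out) > cap)
      stop_mri("DNF expansion of rule '", rule_text, "' exceeds cap of ",
               cap, " disjuncts")
    out
  }
  conj <- rec(node)
  lapply(conj, function(g) sort(unique(g)))
}

gpr_genes <- function(text) {
  node <- gpr_parse(text)
  if (is.null(node)) return(character(0))
  collect <- function(nd) {
    if (!is.null(nd$gene)) return(nd$gene)
    unlist(lapply(nd$args, collect))
  }
  sort(unique(collect(node)))
}

# Render a conjunct vector back to rule text ("g1 and g2", "g1", "").
conjunct_text <- function(genes) {
  if (length(genes) == 0L) return("")
  paste(genes, collapse = " and ")
}

# Render a parse tree back to rule text with conventional precedence:
# AND binds tighter than OR, so AND groups inside an OR get parentheses
# and nothing else does.
gpr_text <- function(node) {
  if (is.null(node)) return("")
  if (!is.null(node$gene)) return(node$gene)
  parts <- vapply(node$args, function(a) {
    txt <- gpr_text(a)
    if (is.null(a$gene) && a$op != node$op)
      paste0("(", txt, ")") else txt
  }, "")
  paste(parts, collapse = paste0(" ", node$op, " "))
}
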