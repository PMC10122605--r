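# File formats: BoolNet-style .bnet, sketch JSON, observation tables, and a
# minimal .aeon-style dialect (read-only).

#' Read and write BoolNet-style `targets, factors` files
#'
#' The file starts with the header `targets, factors` and contains one row
#' per variable: `name, expression`, with fully specified expressions in the
#' package's expression syntax.  Variables are taken in file order.  Writing
#' renders each update function as a disjunction of minterms over its
#' essential inputs; a write/read round trip preserves the truth tables.
#'
#' @param path file path
#' @return a `boolean_network`
#' @export
read_bnet <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("bnet: expected a header and at least one row", call. = FALSE)
  header <- tolower(gsub("\\s", "", lines[[1L]]))
  if (header != "targets,factors") stop("bnet: missing 'targets, factors' header", call. = FALSE)
  rows <- lines[-1L]
  split_at <- regexpr(",", rows, fixed = TRUE)
  if (any(split_at < 0L)) stop("bnet: row without 'target, factor' separator", call. = FALSE)
  targets <- trimws(substr(rows, 1L, split_at - 1L))
  factors <- trimws(substr(rows, split_at + 1L, nchar(rows)))
  if (anyDuplicated(targets)) {
    stop(sprintf("bnet: duplicate target row for '%s'", targets[duplicated(targets)][1L]), call. = FALSE)
  }
  if (!all(is_identifier(targets))) stop("bnet: invalid target name", call. = FALSE)
  exprs <- lapply(factors, parse_expression, variables = targets)
  names(exprs) <- targets
  specialize(psbn(targets, exprs), list())
}

#' @rdname read_bnet
#' @param bn a `boolean_network`
#' @export
write_bnet <- function(bn, path) {
  stopifnot(inherits(bn, "boolean_network"))
  n <- length(bn$variables)
  rows <- vapply(bn$variables, function(v) {
    tab <- bn$tables[[v]]
    regs <- dep_set(tab, bn$variables)
    k <- length(regs)
    if (k == 0L) {
      e <- e_const(tab[1L])
    } else {
      # restrict the full table to the essential inputs (others fixed to 0)
      jj <- match(regs, bn$variables)
      combos <- all_bit_rows(k)
      local <- vapply(seq_len(2^k), function(r) {
        bits <- integer(n)
        bits[jj] <- combos[r, ]
        tab[bits_to_code(bits) + 1L]
      }, logical(1))
      e <- table_to_expression(local, regs)
    }
    sprintf("%s, %s", v, format_expression(e))
  }, "")
  writeLines(c("targets, factors", rows), path)
  invisible(path)
}

#' Read an observation table from CSV/TSV
#'
#' Expected layout: a header row with an experiment-id column followed by
#' variable names; cells are 0, 1 or NA.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated
#' @param kind `"steady_state"` or `"time_series"`
#' @return an `observation_table`
#' @export
read_observations <- function(path, kind = c("steady_state", "time_series")) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("observations: expected an id column plus variables", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  observation_table(m, kind)
}

# --- sketch JSON -------------------------------------------------------------

SKETCH_SCHEMA <- "bnsketch-sketch/1"

#' Read and write sketch JSON
#'
#' The sketch file is a JSON object with fields `variables` (ordered list),
#' `influences` (objects with `regulator`, `target`, and optional `sign` in
#' `+`/`-`/`?` and logical `essential`, which auto-generate update-function
#' properties), `symbols` (name to arity), `update_expressions` (variable to
#' expression string; a variable with no entry defaults to a fresh symbol
#' applied to all its regulators), `properties` (objects with `target` and
#' `property` string) and `hctl` (closed formula strings).
#'
#' @param path file path
#' @return a `bn_sketch`
#' @export
read_sketch <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- vapply(js$variables, as.character, "")
  if (length(vars) == 0L) stop("sketch: missing 'variables' section", call. = FALSE)

  edges <- NULL
  auto_props <- list()
  for (inf in js$influences) {
    if (is.null(inf$regulator) || is.null(inf$target)) {
      stop("sketch: each influence needs 'regulator' and 'target'", call. = FALSE)
    }
    edges <- rbind(edges, c(inf$regulator, inf$target))
    sign <- inf$sign %||% "?"
    essential <- isTRUE(inf$essential)
    atoms <- character(0)
    if (sign == "+") atoms <- c(atoms, sprintf("positive(%s)", inf$regulator))
    if (sign == "-") atoms <- c(atoms, sprintf("negative(%s)", inf$regulator))
    if (essential) atoms <- c(atoms, sprintf("essential(%s)", inf$regulator))
    if (length(atoms)) {
      auto_props <- c(auto_props, list(ufp_item(inf$target, paste(atoms, collapse = " & "))))
    }
  }
  if (is.null(edges)) stop("sketch: missing 'influences' section", call. = FALSE)
  ig <- influence_graph(vars, edges)

  symbols <- data.frame(name = character(0), arity = integer(0))
  for (nm in names(js$symbols)) {
    symbols <- rbind(symbols, data.frame(name = nm, arity = as.integer(js$symbols[[nm]])))
  }
  exprs <- list()
  for (v in vars) {
    txt <- js$update_expressions[[v]]
    if (is.null(txt)) {
      regs <- predecessors(ig, v)
      sym <- paste0("u_", v)
      if (!(sym %in% symbols$name)) {
        symbols <- rbind(symbols, data.frame(name = sym, arity = length(regs)))
      }
      exprs[[v]] <- e_apply(list(name = sym, arity = length(regs)), lapply(regs, e_var))
    } else {
      exprs[[v]] <- as.character(txt)
    }
  }
  net <- tryCatch(psbn(vars, exprs, symbols),
                  error = function(e) stop(sprintf("sketch: invalid 'update_expressions': %s",
                                                   conditionMessage(e)), call. = FALSE))
  props <- auto_props
  for (pr in js$properties) {
    if (is.null(pr$target) || is.null(pr$property)) {
      stop("sketch: each property needs 'target' and 'property'", call. = FALSE)
    }
    props <- c(props, list(ufp_item(as.character(pr$target), as.character(pr$property))))
  }
  dyn <- lapply(js$hctl, as.character)
  tryCatch(bn_sketch(ig, net, props, dyn),
           error = function(e) stop(sprintf("sketch: %s", conditionMessage(e)), call. = FALSE))
}

#' @rdname read_sketch
#' @param sketch a `bn_sketch`
#' @export
write_sketch <- function(sketch, path) {
  stopifnot(inherits(sketch, "bn_sketch"))
  net <- sketch$network
  out <- list(
    schema = SKETCH_SCHEMA,
    variables = as.list(net$variables),
    influences = lapply(seq_len(nrow(sketch$ig$edges)), function(i) {
      list(regulator = sketch$ig$edges[i, "regulator"],
           target = sketch$ig$edges[i, "target"])
    }),
    symbols = stats::setNames(as.list(net$symbols$arity), net$symbols$name),
    update_expressions = lapply(net$expressions, format_expression),
    properties = lapply(sketch$properties, function(it) {
      list(target = it$target, property = format_property(it$property))
    }),
    hctl = lapply(sketch$dynamics, format_hctl)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a minimal .aeon-style model (read-only)
#'
#' Supported lines: regulations `a -> b`, `a -| b` (activation/inhibition),
#' with `?` appended for non-observable edges (`a ->? b`) and `a -? b` for
#' unknown sign; update functions `$v: expression`; `#` comments.  Signed
#' observable edges generate the corresponding monotonicity/essentiality
#' properties; variables without an update function default to a fresh
#' uninterpreted symbol over their regulators.
#'
#' @param path file path
#' @return a `bn_sketch` (with no dynamic properties)
#' @export
read_aeon <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  reg_pat <- "^([A-Za-z_][A-Za-z0-9_]*)\\s*(->\\??|-\\|\\??|-\\?)\\s*([A-Za-z_][A-Za-z0-9_]*)$"
  fun_pat <- "^\\$\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$"
  edges <- NULL; props <- list(); updates <- list()
  for (ln in lines) {
    if (grepl(reg_pat, ln)) {
      m <- regmatches(ln, regexec(reg_pat, ln))[[1L]]
      from <- m[2L]; op <- m[3L]; to <- m[4L]
      edges <- rbind(edges, c(from, to))
      observable <- !endsWith(op, "?")
      atoms <- character(0)
      if (startsWith(op, "->")) atoms <- sprintf("positive(%s)", from)
      if (startsWith(op, "-|")) atoms <- sprintf("negative(%s)", from)
      if (observable && op != "-?") atoms <- c(atoms, sprintf("essential(%s)", from))
      if (length(atoms)) props <- c(props, list(ufp_item(to, paste(atoms, collapse = " & "))))
    } else if (grepl(fun_pat, ln)) {
      m <- regmatches(ln, regexec(fun_pat, ln))[[1L]]
      updates[[m[2L]]] <- m[3L]
    } else {
      stop(sprintf("aeon: cannot parse line '%s'", ln), call. = FALSE)
    }
  }
  if (is.null(edges)) stop("aeon: no regulations found", call. = FALSE)
  vars <- sort(unique(c(edges, names(updates))))
  ig <- influence_graph(vars, edges)
  # collect symbols used by explicit updates: declared implicitly as name(args)
  symbols <- data.frame(name = character(0), arity = integer(0))
  exprs <- list()
  for (v in vars) {
    txt <- updates[[v]]
    if (is.null(txt)) {
      regs <- predecessors(ig, v)
      sym <- paste0("u_", v)
      symbols <- rbind(symbols, data.frame(name = sym, arity = length(regs)))
      exprs[[v]] <- e_apply(list(name = sym, arity = length(regs)), lapply(regs, e_var))
    } else {
      # infer symbol declarations from application sites: name(arg, ...)
      ids <- gregexpr("[A-Za-z_][A-Za-z0-9_]*\\s*\\(", txt)[[1L]]
      if (ids[1L] != -1L) {
        for (k in seq_along(ids)) {
          nm <- sub("\\s*\\($", "", regmatches(txt, ids)[[1L]][k])
          if (!(nm %in% vars) && !(nm %in% symbols$name)) {
            open <- ids[k] + attr(ids, "match.length")[k] - 1L
            depth <- 1L; j <- open; commas <- 0L
            while (depth > 0L && j < nchar(txt)) {
              j <- j + 1L
              ch <- substr(txt, j, j)
              if (ch == "(") depth <- depth + 1L
              if (ch == ")") depth <- depth - 1L
              if (ch == "," && depth == 1L) commas <- commas + 1L
            }
            arity <- if (j == open + 1L) 0L else commas + 1L
            symbols <- rbind(symbols, data.frame(name = nm, arity = arity))
          }
        }
      }
      exprs[[v]] <- txt
    }
  }
  bn_sketch(ig, psbn(vars, exprs, symbols), props, list())
}
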