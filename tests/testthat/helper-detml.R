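# shared test helpers

findings_df <- function(report) {
  if (!length(report$findings)) {
    return(data.frame(rule_id = character(0), line = integer(0)))
  }
  data.frame(
    rule_id = vapply(report$findings, `[[`, "", "rule_id"),
    line = vapply(report$findings, `[[`, 1L, "line"),
    stringsAsFactors = FALSE
  )
}

# set-of-(rule id, line) equality between a lint report and expectations
expect_findings_equal <- function(report, expected) {
  got <- findings_df(report)
  expect_setequal(paste(got$rule_id, got$line),
                  paste(expected$rule_id, expected$line))
}

# Independent oracle: Python's own ast module, walking a snippet and
# resolving import aliases the same way a reader of the code would.
# Returns a data.frame (qualified, line) of resolved call sites.
python_ast_call_sites <- function(source) {
  script <- '
import ast, json, sys
src = sys.stdin.read()
tree = ast.parse(src)
aliases = {}
for node in ast.walk(tree):
    if isinstance(node, ast.Import):
        for a in node.names:
            aliases[a.asname or a.name.split(".")[0]] = (
                a.name if a.asname else a.name.split(".")[0])
    elif isinstance(node, ast.ImportFrom) and node.module and node.level == 0:
        for a in node.names:
            if a.name != "*":
                aliases[a.asname or a.name] = node.module + "." + a.name
def qual(node):
    if isinstance(node, ast.Name):
        return aliases.get(node.id, node.id)
    if isinstance(node, ast.Attribute):
        base = qual(node.value)
        return None if base is None else base + "." + node.attr
    return None
out = []
for node in ast.walk(tree):
    if isinstance(node, ast.Call):
        q = qual(node.func)
        if q is not None:
            out.append({"qualified": q, "line": node.lineno})
print(json.dumps(out))
'
  out <- system2("python", c("-c", shQuote(script)), input = source,
                 stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""),
                               simplifyDataFrame = TRUE)
  if (length(parsed) == 0) {
    return(data.frame(qualified = character(0), line = integer(0)))
  }
  parsed[order(parsed$line, parsed$qualified), , drop = FALSE]
}
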