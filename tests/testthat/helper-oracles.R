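# independent transcription of the ACMG/AMP combining tables, written as
# literal pattern lists; serves as the oracle for combine_acmg
oracle_combine <- function(codes) {
  cnt <- function(pat) sum(grepl(pat, codes))
  n <- c(pvs = sum(codes == "PVS1"), ps = cnt("^PS"), pm = cnt("^PM"),
         pp = cnt("^PP"), ba = sum(codes == "BA1"), bs = cnt("^BS"),
         bp = cnt("^BP"))
  sat <- function(patterns) any(vapply(patterns, function(p)
    all(n[names(p)] >= p), logical(1)))
  p_rules <- sat(list(c(pvs = 1, ps = 1), c(pvs = 1, pm = 2),
                      c(pvs = 1, pm = 1, pp = 1), c(pvs = 1, pp = 2),
                      c(ps = 2), c(ps = 1, pm = 3),
                      c(ps = 1, pm = 2, pp = 2), c(ps = 1, pm = 1, pp = 4)))
  lp_rules <- sat(list(c(pvs = 1, pm = 1), c(ps = 1, pm = 1),
                       c(ps = 1, pp = 2), c(pm = 3), c(pm = 2, pp = 2),
                       c(pm = 1, pp = 4)))
  b_rules <- sat(list(c(ba = 1), c(bs = 2)))
  lb_rules <- sat(list(c(bs = 1, bp = 1), c(bp = 2)))
  if ((p_rules || lp_rules) && (b_rules || lb_rules)) return("VUS")
  if (p_rules) return("P")
  if (lp_rules) return("LP")
  if (b_rules) return("B")
  if (lb_rules) return("LB")
  "VUS"
}
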