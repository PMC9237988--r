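#include <Rcpp.h>
using namespace Rcpp;

// CIGAR parser shared by the batch routines. Throws on malformed input.
static void parse_cigar(const char* c, std::vector<int>& lens,
                        std::vector<char>& ops) {
  lens.clear();
  ops.clear();
  long v = 0;
  bool have = false;
  for (const char* p = c; *p; ++p) {
    char ch = *p;
    if (ch >= '0' && ch <= '9') {
      v = v * 10 + (ch - '0');
      have = true;
    } else {
      if (!have) stop("malformed CIGAR: %s", c);
      lens.push_back((int)v);
      ops.push_back(ch);
      v = 0;
      have = false;
    }
  }
  if (have) stop("malformed CIGAR: %s", c);
}

static inline char upper(char b) {
  return (b >= 'a' && b <= 'z') ? b - 32 : b;
}

// Build an MD tag and NM count for a (possibly rewritten) sequence against
// the reference. Follows the SAM optional-field spec: numbers (possibly 0)
// separate every mismatch/deletion token.
static void make_md(const std::string& seq,
                    const std::vector<int>& lens, const std::vector<char>& ops,
                    const char* ref, size_t reflen, int pos0,
                    std::string& md, int& nm) {
  md.clear();
  nm = 0;
  int run = 0;
  size_t qi = 0;
  long rp = pos0;
  for (size_t k = 0; k < ops.size(); ++k) {
    char op = ops[k];
    int len = lens[k];
    if (op == 'M' || op == '=' || op == 'X') {
      for (int j = 0; j < len; ++j) {
        char rb = (rp >= 0 && (size_t)rp < reflen) ? upper(ref[rp]) : 'N';
        char b = upper(seq[qi]);
        if (b == rb) {
          ++run;
        } else {
          md += std::to_string(run);
          md += rb;
          run = 0;
          ++nm;
        }
        ++qi;
        ++rp;
      }
    } else if (op == 'I') {
      qi += len;
      nm += len;
    } else if (op == 'S') {
      qi += len;
    } else if (op == 'D') {
      md += std::to_string(run);
      run = 0;
      md += '^';
      for (int j = 0; j < len; ++j) {
        char rb = (rp >= 0 && (size_t)rp < reflen) ? upper(ref[rp]) : 'N';
        md += rb;
        ++rp;
      }
      nm += len;
    } else if (op == 'N') {
      rp += len;
    }
    // H and P consume nothing relevant to MD/NM
  }
  md += std::to_string(run);
}

// Double-mask a batch of records in place. context: 0 = leave untouched,
// 1 = CT (read T may be converted C), 2 = GA. scope: 1 = BQ-zero every
// convertible read base, 2 = only those at replaced (ref-C/read-T or
// ref-G/read-A) aligned columns. refIdx is the 1-based index into refs for
// each record (NA only allowed when context is 0).
// [[Rcpp::export]]
List cpp_mask_batch(CharacterVector seqs, CharacterVector quals,
                    CharacterVector cigars, IntegerVector pos0,
                    IntegerVector context, CharacterVector refs,
                    IntegerVector refIdx, int scope, bool recompute) {
  int n = seqs.size();
  CharacterVector out_seq(n), out_qual(n), out_md(n);
  IntegerVector out_nm(n), replaced(n), zeroed(n);
  std::vector<int> lens;
  std::vector<char> ops;
  std::string md;

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    int ctx = context[i];
    if (ctx == 0 || s == "*") {
      out_seq[i] = s;
      out_qual[i] = q;
      out_md[i] = NA_STRING;
      out_nm[i] = NA_INTEGER;
      continue;
    }
    if (refIdx[i] == NA_INTEGER)
      stop("no reference source for record %d", i + 1);
    const char* ref = CHAR(STRING_ELT(refs, refIdx[i] - 1));
    size_t reflen = strlen(ref);
    parse_cigar(CHAR(STRING_ELT(cigars, i)), lens, ops);
    if (q.size() != s.size())
      stop("seq/qual length mismatch at record %d", i + 1);

    char target = (ctx == 1) ? 'T' : 'A';
    char reftgt = (ctx == 1) ? 'C' : 'G';
    int nrep = 0, nzero = 0;
    size_t qi = 0;
    long rp = pos0[i];
    for (size_t k = 0; k < ops.size(); ++k) {
      char op = ops[k];
      int len = lens[k];
      if (op == 'M' || op == '=' || op == 'X') {
        for (int j = 0; j < len; ++j) {
          char b = upper(s[qi]);
          if (b == target) {
            char rb = (rp >= 0 && (size_t)rp < reflen) ? upper(ref[rp]) : 'N';
            if (rb == reftgt) {
              s[qi] = reftgt;
              q[qi] = '!';
              ++nrep;
              ++nzero;
            } else if (scope == 1) {
              q[qi] = '!';
              ++nzero;
            }
          }
          ++qi;
          ++rp;
        }
      } else if (op == 'I' || op == 'S') {
        for (int j = 0; j < len; ++j) {
          if (scope == 1 && upper(s[qi]) == target) {
            q[qi] = '!';
            ++nzero;
          }
          ++qi;
        }
      } else if (op == 'D' || op == 'N') {
        rp += len;
      }
    }
    out_seq[i] = s;
    out_qual[i] = q;
    replaced[i] = nrep;
    zeroed[i] = nzero;
    if (recompute) {
      int nm;
      make_md(s, lens, ops, ref, reflen, pos0[i], md, nm);
      out_md[i] = md;
      out_nm[i] = nm;
    } else {
      out_md[i] = NA_STRING;
      out_nm[i] = NA_INTEGER;
    }
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["replaced"] = replaced, _["zeroed"] = zeroed,
                      _["md"] = out_md, _["nm"] = out_nm);
}

static inline int base_code(char b) {
  switch (upper(b)) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 3;
  case 'T': return 4;
  default: return 0;
  }
}

// Expand a batch of records into flat per-base column vectors. Reference
// bases come from the contig sequences (refIdx 1-based; NA yields refCode 0
// everywhere). rpos0 is -1 for insertions/soft-clips.
// [[Rcpp::export]]
List cpp_columns(CharacterVector seqs, CharacterVector quals,
                 CharacterVector cigars, IntegerVector pos0,
                 CharacterVector refs, IntegerVector refIdx) {
  int n = seqs.size();
  std::vector<int> lens;
  std::vector<char> ops;
  // first pass: total query length
  R_xlen_t total = 0;
  for (int i = 0; i < n; ++i) {
    const char* sp = CHAR(STRING_ELT(seqs, i));
    if (strcmp(sp, "*") == 0) continue;
    total += strlen(sp);
  }
  IntegerVector rec(total), qpos0(total), rpos0(total), baseCode(total),
      bq(total), refCode(total);
  R_xlen_t o = 0;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if (strcmp(s, "*") == 0) continue;
    const char* q = CHAR(STRING_ELT(quals, i));
    size_t slen = strlen(s);
    bool have_q = strlen(q) == slen;
    const char* ref = NULL;
    size_t reflen = 0;
    if (refIdx[i] != NA_INTEGER) {
      ref = CHAR(STRING_ELT(refs, refIdx[i] - 1));
      reflen = strlen(ref);
    }
    parse_cigar(CHAR(STRING_ELT(cigars, i)), lens, ops);
    size_t qi = 0;
    long rp = pos0[i];
    for (size_t k = 0; k < ops.size(); ++k) {
      char op = ops[k];
      int len = lens[k];
      if (op == 'M' || op == '=' || op == 'X') {
        for (int j = 0; j < len; ++j) {
          rec[o] = i + 1;
          qpos0[o] = (int)qi;
          rpos0[o] = (int)rp;
          baseCode[o] = base_code(s[qi]);
          bq[o] = have_q ? (int)q[qi] - 33 : NA_INTEGER;
          refCode[o] = (ref && rp >= 0 && (size_t)rp < reflen)
                           ? base_code(ref[rp]) : 0;
          ++o;
          ++qi;
          ++rp;
        }
      } else if (op == 'I' || op == 'S') {
        for (int j = 0; j < len; ++j) {
          rec[o] = i + 1;
          qpos0[o] = (int)qi;
          rpos0[o] = -1;
          baseCode[o] = base_code(s[qi]);
          bq[o] = have_q ? (int)q[qi] - 33 : NA_INTEGER;
          refCode[o] = 0;
          ++o;
          ++qi;
        }
      } else if (op == 'D' || op == 'N') {
        rp += len;
      }
    }
    if (qi != slen)
      stop("CIGAR query length does not match sequence at record %d", i + 1);
  }
  return List::create(_["rec"] = rec, _["qpos0"] = qpos0, _["rpos0"] = rpos0,
                      _["baseCode"] = baseCode, _["bq"] = bq,
                      _["refCode"] = refCode);
}

// MD/NM for a batch of arbitrary-CIGAR records against contig sequences.
// [[Rcpp::export]]
List cpp_md_batch(CharacterVector seqs, CharacterVector cigars,
                  IntegerVector pos0, CharacterVector refs,
                  IntegerVector refIdx) {
  int n = seqs.size();
  CharacterVector out_md(n);
  IntegerVector out_nm(n);
  std::vector<int> lens;
  std::vector<char> ops;
  std::string md;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s == "*" || refIdx[i] == NA_INTEGER) {
      out_md[i] = NA_STRING;
      out_nm[i] = NA_INTEGER;
      continue;
    }
    const char* ref = CHAR(STRING_ELT(refs, refIdx[i] - 1));
    parse_cigar(CHAR(STRING_ELT(cigars, i)), lens, ops);
    int nm;
    make_md(s, lens, ops, ref, strlen(ref), pos0[i], md, nm);
    out_md[i] = md;
    out_nm[i] = nm;
  }
  return List::create(_["md"] = out_md, _["nm"] = out_nm);
}
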