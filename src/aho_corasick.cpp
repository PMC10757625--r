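// Multi-pattern exact matcher for amino-acid sequences.
//
// Classic Aho-Corasick automaton over the byte alphabet A-Z. Characters
// outside A-Z (stop '*', gaps, etc.) reset the scan to the root, so matches
// can never cross them. All overlapping occurrences are reported. Patterns
// are assumed upper-cased by the caller.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <string>
#include <cstring>

using namespace Rcpp;

namespace {

const int SIGMA = 26;

struct Automaton {
  // goto function, flat: states * SIGMA
  std::vector<int> go;
  std::vector<int> fail;
  // pattern index ending at this state (-1 if none); patterns are unique
  std::vector<int> out;
  // dictionary suffix link: nearest proper suffix state with output
  std::vector<int> dict;
  std::vector<int> depth;

  int new_state(int d) {
    go.insert(go.end(), SIGMA, -1);
    fail.push_back(0);
    out.push_back(-1);
    dict.push_back(0);
    depth.push_back(d);
    return static_cast<int>(fail.size()) - 1;
  }
};

inline int code(char c) {
  // 'X' (unknown residue) and anything outside A-Z never matches
  if (c < 'A' || c > 'Z' || c == 'X') return -1;
  return c - 'A';
}

void build(Automaton& ac, const std::vector<std::string>& patterns) {
  ac.new_state(0);  // root = 0
  for (size_t p = 0; p < patterns.size(); ++p) {
    int s = 0;
    for (char ch : patterns[p]) {
      int c = code(ch);
      if (c < 0) Rcpp::stop("pattern contains a non-matchable character");
      int nxt = ac.go[s * SIGMA + c];
      if (nxt < 0) {
        nxt = ac.new_state(ac.depth[s] + 1);
        ac.go[s * SIGMA + c] = nxt;
      }
      s = nxt;
    }
    ac.out[s] = static_cast<int>(p);
  }
  // BFS to set failure links and complete goto into a DFA
  std::queue<int> q;
  for (int c = 0; c < SIGMA; ++c) {
    int s = ac.go[c];
    if (s < 0) {
      ac.go[c] = 0;
    } else {
      ac.fail[s] = 0;
      q.push(s);
    }
  }
  while (!q.empty()) {
    int s = q.front();
    q.pop();
    int f = ac.fail[s];
    ac.dict[s] = (ac.out[f] >= 0) ? f : ac.dict[f];
    for (int c = 0; c < SIGMA; ++c) {
      int nxt = ac.go[s * SIGMA + c];
      if (nxt < 0) {
        ac.go[s * SIGMA + c] = ac.go[f * SIGMA + c];
      } else {
        ac.fail[nxt] = ac.go[f * SIGMA + c];
        q.push(nxt);
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".ac_search")]]
List ac_search(CharacterVector texts, CharacterVector patterns) {
  std::vector<std::string> pats(patterns.size());
  size_t total_len = 0;
  for (R_xlen_t i = 0; i < patterns.size(); ++i) {
    pats[i] = as<std::string>(patterns[i]);
    if (pats[i].empty()) Rcpp::stop("empty pattern");
    total_len += pats[i].size();
  }
  Automaton ac;
  ac.go.reserve((total_len + 1) * SIGMA);
  build(ac, pats);

  std::vector<int> r_text, r_pattern, r_start;
  for (R_xlen_t t = 0; t < texts.size(); ++t) {
    const char* s = CHAR(STRING_ELT(texts, t));
    int state = 0;
    for (size_t i = 0; s[i] != '\0'; ++i) {
      int c = code(s[i]);
      if (c < 0) {
        state = 0;
        continue;
      }
      state = ac.go[state * SIGMA + c];
      for (int u = (ac.out[state] >= 0 ? state : ac.dict[state]); u != 0;
           u = ac.dict[u]) {
        int p = ac.out[u];
        r_text.push_back(static_cast<int>(t) + 1);
        r_pattern.push_back(p + 1);
        // 1-based start of the occurrence
        r_start.push_back(static_cast<int>(i) + 2 - ac.depth[u]);
      }
    }
    if ((t & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["text"] = wrap(r_text),
                      _["pattern"] = wrap(r_pattern),
                      _["start"] = wrap(r_start));
}
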