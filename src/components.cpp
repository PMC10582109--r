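#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labels from an undirected edge list via union-find.
// Nodes are 1..n; edges given as parallel index vectors. Labels are
// renumbered 1..k in order of first appearance (deterministic).
// [[Rcpp::export]]
IntegerVector uf_components(int n, IntegerVector ei, IntegerVector ej) {
    std::vector<int> parent(n);
    for (int i = 0; i < n; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int x) {
        while (parent[x] != x) {
            parent[x] = parent[parent[x]];
            x = parent[x];
        }
        return x;
    };
    int m = ei.size();
    for (int e = 0; e < m; ++e) {
        int a = find(ei[e] - 1), b = find(ej[e] - 1);
        if (a != b) parent[std::max(a, b)] = std::min(a, b);
    }
    IntegerVector lab(n);
    std::vector<int> newlab(n, 0);
    int k = 0;
    for (int i = 0; i < n; ++i) {
        int r = find(i);
        if (newlab[r] == 0) newlab[r] = ++k;
        lab[i] = newlab[r];
    }
    return lab;
}
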