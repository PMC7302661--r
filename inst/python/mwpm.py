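"""Exact minimum-weight perfect matching on complete graphs.

Reads JSON from stdin: a list of instances, each {"n": <int>, "d": [...]},
where d is the full n x n distance matrix flattened row-major. Writes JSON
to stdout: a list of pairings, each a list of [i, j] 0-based index pairs.
"""
import json
import sys

import networkx as nx


def solve(n, flat):
    g = nx.Graph()
    g.add_nodes_from(range(n))
    for i in range(n):
        for j in range(i + 1, n):
            g.add_edge(i, j, weight=flat[i * n + j])
    match = nx.min_weight_matching(g)
    return sorted(sorted(pair) for pair in match)


def main():
    instances = json.load(sys.stdin)
    out = [solve(int(inst["n"]), inst["d"]) for inst in instances]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
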