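X is a Y
X is a potent Y
X are Y
X is the most common Y
X and other Y
X are rare Y
X as a Y
X is a widely used Y
X such as Y
X is an uncommon Y
X is an Y
X is an autosomal dominant Y
X as an Y
X is a form of Y
X is an important Y
X is one of the major Y
X a new Y
X is a chronic Y
X are the most common Y
X and other forms of Y
X is a rare Y
X is a broad spectrum Y
X is a novel Y
X is the primary Y
X is a major Y
X is a rare autosomal recessive Y
X is an essential Y
X is the most common type of Y
X was the only Y
X is the second most common Y
X was the most common Y
X are the most frequent Y
X is a common Y
X is the most widely used Y
X is a new Y
X is the most frequent Y
X is a complex Y
X is the most common primary Y
X is an effective Y
X is one of the major Y
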